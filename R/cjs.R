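## Cormack-Jolly-Seber apparent survival: encounter histories, likelihood,
## maximum-likelihood fitting, AICc model selection.

month_index <- function(dates, start_month) {
  d <- as.Date(paste0(format(as.Date(dates), "%Y-%m"), "-01"))
  s <- as.Date(paste0(start_month, "-01"))
  12L * (as.integer(format(d, "%Y")) - as.integer(format(s, "%Y"))) +
    (as.integer(format(d, "%m")) - as.integer(format(s, "%m"))) + 1L
}

#' Construct an encounter-histories object
#'
#' Container for Cormack-Jolly-Seber input: a 0/1 matrix `h` (birds x
#' occasions), the release occasion `f` per bird (first 1), and the
#' individual covariates `sex` (`"F"`/`"M"`) and `adult` (1 = AHY).
#' `occasion_months` (`"YYYY-MM"`) drives the seasonal covariate.
#'
#' @param h integer 0/1 matrix, one row per bird.
#' @param tag_id,sex,adult per-bird vectors (recycled NA if omitted).
#' @param occasion_months character vector, one `"YYYY-MM"` per occasion.
#' @return list of class `"encounter_histories"`.
#' @export
encounter_histories <- function(h, tag_id = NULL, sex = NULL, adult = NULL,
                                occasion_months = NULL) {
  h <- as.matrix(h)
  storage.mode(h) <- "integer"
  n <- nrow(h)
  if (is.null(tag_id)) tag_id <- sprintf("B%04d", seq_len(n))
  f <- apply(h, 1L, function(r) which(r == 1L)[1L])
  if (anyNA(f)) stop("history with no detections at all", call. = FALSE)
  structure(list(h = h, tag_id = tag_id, f = as.integer(f),
                 sex = if (is.null(sex)) rep(NA_character_, n) else sex,
                 adult = if (is.null(adult)) rep(NA_integer_, n) else
                   as.integer(adult),
                 occasion_months = occasion_months),
            class = "encounter_histories")
}

#' Build monthly encounter histories from a detection log
#'
#' Divides the study window into `n_occasions` month-long samples starting
#' at `start_month` and records, per bird, whether it was detected at
#' least once in each month.  The tagging month is the release occasion:
#' the capture itself counts as the first encounter, so `h[f] = 1` even
#' without an RFID read that month.  Birds whose tagging month falls
#' outside the window are excluded with a warning.
#'
#' @param detections detection table.
#' @param roster roster table.
#' @param start_month `"YYYY-MM"` of occasion 1.
#' @param n_occasions number of monthly occasions (default 13).
#' @param cohort_filter optional predicate `function(roster) -> logical`
#'   selecting the birds to include (e.g. tagged at one site).
#' @return an [encounter_histories()] object.
#' @export
build_encounter_histories <- function(detections, roster, start_month,
                                      n_occasions = 13,
                                      cohort_filter = NULL) {
  r <- roster
  if (!is.null(cohort_filter)) r <- r[cohort_filter(r), , drop = FALSE]
  rel <- month_index(r$tag_date, start_month)
  out_of_window <- rel < 1L | rel > n_occasions
  if (any(out_of_window)) {
    warning(sum(out_of_window),
            " bird(s) tagged outside the occasion window were excluded")
    r <- r[!out_of_window, , drop = FALSE]
    rel <- rel[!out_of_window]
  }
  h <- matrix(0L, nrow(r), n_occasions)
  d <- detections[detections$tag_id %in% r$tag_id, , drop = FALSE]
  if (nrow(d)) {
    mi <- month_index(as.Date(d$timestamp), start_month)
    ok <- mi >= 1L & mi <= n_occasions
    bi <- match(d$tag_id[ok], r$tag_id)
    h[cbind(bi, mi[ok])] <- 1L
  }
  h[cbind(seq_len(nrow(r)), rel)] <- 1L
  # release = tagging month, even if earlier RFID reads exist (they cannot)
  start <- as.Date(paste0(start_month, "-01"))
  occ <- format(seq(start, by = "month", length.out = n_occasions), "%Y-%m")
  encounter_histories(h, tag_id = r$tag_id, sex = r$sex,
                      adult = ifelse(r$age == "UNKNOWN", NA_integer_,
                                     as.integer(r$age == "AHY")),
                      occasion_months = occ)
}

group_order <- c("F-AHY", "F-HY", "M-AHY", "M-HY")

#' Write encounter histories as a MARK .inp file
#'
#' One line per bird: the 0/1 history string, a frequency column per
#' sex-by-age group in the fixed order F-AHY, F-HY, M-AHY, M-HY, and a
#' terminating `";"`.  [read_mark_inp()] is the lossless inverse.
#'
#' @param histories an [encounter_histories()] object (sex and adult must
#'   be non-missing).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mark_inp <- function(histories, path) {
  h <- histories$h
  grp <- paste0(histories$sex, "-", ifelse(histories$adult == 1L, "AHY", "HY"))
  if (anyNA(histories$sex) || anyNA(histories$adult))
    stop("sex/adult covariates required to write .inp groups", call. = FALSE)
  lines <- vapply(seq_len(nrow(h)), function(i) {
    freq <- as.integer(group_order == grp[i])
    paste(paste(h[i, ], collapse = ""), paste(freq, collapse = " "), ";")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a MARK .inp file written by [write_mark_inp()]
#'
#' @param path input path.
#' @return an [encounter_histories()] object.
#' @export
read_mark_inp <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hs <- list(); sexes <- character(); adults <- integer()
  for (i in seq_along(lines)) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (toks[length(toks)] != ";")
      stop("malformed .inp line ", i, ": missing ';'", call. = FALSE)
    hstr <- toks[1L]
    freq <- as.integer(toks[2:(length(toks) - 1L)])
    if (length(freq) != 4L || sum(freq) != 1L || anyNA(freq))
      stop("malformed .inp line ", i, ": bad group frequencies",
           call. = FALSE)
    g <- group_order[freq == 1L]
    hs[[i]] <- as.integer(strsplit(hstr, "")[[1]])
    sexes[i] <- sub("-.*", "", g)
    adults[i] <- as.integer(endsWith(g, "AHY"))
  }
  if (length(unique(lengths(hs))) > 1L)
    stop("ragged encounter histories in .inp", call. = FALSE)
  encounter_histories(do.call(rbind, hs), sex = sexes, adult = adults)
}

#' Cormack-Jolly-Seber log-likelihood
#'
#' Conditional-on-first-release CJS likelihood.  For bird `i` released at
#' occasion `f` and last seen at `l`, the contribution is
#' `prod_{t=f}^{l-1} phi[i,t] * (p[i,t] if h[i,t+1]=1 else 1-p[i,t])`
#' times the never-seen-again term `chi[i,l]`, where
#' `chi[,T] = 1`, `chi[,t] = (1-phi[,t]) + phi[,t]*(1-p[,t])*chi[,t+1]`.
#' `phi[, t]` is survival over interval t -> t+1 and `p[, t]` detection at
#' occasion t+1 (both `n x (T-1)` matrices).
#'
#' @param histories an [encounter_histories()] object.
#' @param phi,p survival and detection probabilities; scalars or
#'   `n x (T-1)` matrices.
#' @return total log-likelihood (may be `-Inf` when an observed event has
#'   probability 0).
#' @export
cjs_loglik <- function(histories, phi, p) {
  h <- histories$h; f <- histories$f
  n <- nrow(h); T <- ncol(h)
  if (length(phi) == 1L) phi <- matrix(phi, n, T - 1L)
  if (length(p) == 1L) p <- matrix(p, n, T - 1L)
  chi <- matrix(1, n, T)
  for (t in (T - 1L):1L)
    chi[, t] <- (1 - phi[, t]) + phi[, t] * (1 - p[, t]) * chi[, t + 1L]
  l <- apply(h, 1L, function(r) max(which(r == 1L)))
  h2 <- h[, -1L, drop = FALSE]
  at_risk <- outer(f, seq_len(T - 1L), "<=") &
             outer(l, seq_len(T - 1L), ">")
  term <- log(phi) + ifelse(h2 == 1L, log(p), log1p(-p))
  ll <- sum(term[at_risk]) + sum(log(chi[cbind(seq_len(n), l)]))
  if (is.nan(ll)) -Inf else ll
}

season_of_month <- function(ym) {
  ifelse(as.integer(sub(".*-", "", ym)) %in% c(12L, 1L, 2L),
         "WINTER", "OTHER")
}

# Long-format covariate frame for the T-1 intervals/occasions 2..T of each
# bird.  `season` is the season of the interval's starting month for phi
# and of the occasion's own month for p.
cjs_design <- function(histories, formula, role = c("phi", "p")) {
  role <- match.arg(role)
  h <- histories$h; n <- nrow(h); T <- ncol(h)
  occ <- histories$occasion_months
  season_int <- if (!is.null(occ)) {
    if (role == "phi") season_of_month(occ[1:(T - 1L)])
    else season_of_month(occ[2:T])
  } else rep("OTHER", T - 1L)
  dat <- data.frame(
    sex = factor(rep(histories$sex, each = T - 1L), levels = c("F", "M")),
    adult = rep(histories$adult, each = T - 1L),
    season = factor(rep(season_int, times = n),
                    levels = c("OTHER", "WINTER")))
  model.matrix(formula, model.frame(formula, dat, na.action = NULL))
}

model_label <- function(phi_formula, p_formula) {
  fs <- function(f) paste(deparse(f), collapse = "")
  sprintf("Phi(%s) p(%s)", fs(phi_formula), fs(p_formula))
}

#' Fit a Cormack-Jolly-Seber model by maximum likelihood
#'
#' Survival and detection are modelled on the logit scale with formulas
#' over the covariates `sex`, `adult` (1 = after-hatch-year) and `season`
#' (`WINTER` = Dec-Feb vs `OTHER`; interval-level for survival,
#' occasion-level for detection).  Coefficients start at zero
#' (probabilities 0.5) and are estimated by BFGS; standard errors come
#' from the numerically differentiated Hessian.  Birds with missing
#' values in any covariate used by either formula are dropped with a
#' warning.  Linear predictors beyond +/-10 on the logit scale are
#' flagged as boundary estimates.
#'
#' @param histories an [encounter_histories()] object.
#' @param phi_formula,p_formula model formulas, e.g. `~1`, `~adult`,
#'   `~season + sex + adult`.
#' @param ess effective sample size for AICc; default the number of
#'   usable histories (one release per bird).
#' @param control passed to [stats::optim()].
#' @return an object of class `"cjs_fit"`.
#' @export
fit_cjs <- function(histories, phi_formula = ~1, p_formula = ~1,
                    ess = NULL,
                    control = list(maxit = 1000, reltol = 1e-10)) {
  vars <- unique(c(all.vars(phi_formula), all.vars(p_formula)))
  keep <- rep(TRUE, nrow(histories$h))
  if ("sex" %in% vars) keep <- keep & !is.na(histories$sex)
  if ("adult" %in% vars) keep <- keep & !is.na(histories$adult)
  if (!all(keep)) {
    warning(sum(!keep), " history(ies) with missing covariates dropped")
    histories <- encounter_histories(histories$h[keep, , drop = FALSE],
                                     tag_id = histories$tag_id[keep],
                                     sex = histories$sex[keep],
                                     adult = histories$adult[keep],
                                     occasion_months = histories$occasion_months)
  }
  n <- nrow(histories$h); T <- ncol(histories$h)
  if (!n) stop("no usable histories", call. = FALSE)
  Xphi <- cjs_design(histories, phi_formula, "phi")
  Xp <- cjs_design(histories, p_formula, "p")
  kphi <- ncol(Xphi); kp <- ncol(Xp)
  negll <- function(beta) {
    phi <- matrix(plogis(Xphi %*% beta[seq_len(kphi)]), n, T - 1L,
                  byrow = TRUE)
    p <- matrix(plogis(Xp %*% beta[kphi + seq_len(kp)]), n, T - 1L,
                byrow = TRUE)
    val <- -cjs_loglik(histories, phi, p)
    if (!is.finite(val)) 1e10 else val
  }
  fit <- optim(rep(0, kphi + kp), negll, method = "BFGS",
               control = control, hessian = TRUE)
  beta <- fit$par
  names(beta) <- c(paste0("phi:", colnames(Xphi)),
                   paste0("p:", colnames(Xp)))
  se <- tryCatch(sqrt(diag(solve(fit$hessian))),
                 error = function(e) rep(NA_real_, length(beta)))
  names(se) <- names(beta)
  eta <- c(Xphi %*% beta[seq_len(kphi)], Xp %*% beta[kphi + seq_len(kp)])
  K <- kphi + kp
  if (is.null(ess)) ess <- n
  ll <- -fit$value
  real <- cjs_real_estimates(beta, se, fit$hessian, Xphi, Xp, kphi, kp)
  structure(list(phi_formula = phi_formula, p_formula = p_formula,
                 model = model_label(phi_formula, p_formula),
                 beta = beta, se = se, logLik = ll, K = K, ess = ess,
                 n = n, AICc = aicc(ll, K, ess),
                 converged = fit$convergence == 0,
                 boundary = any(abs(eta) > 10),
                 real = real),
            class = "cjs_fit")
}

# Real-scale (probability) estimates for each distinct design row, with
# delta-method SEs from the full covariance matrix.
cjs_real_estimates <- function(beta, se, hessian, Xphi, Xp, kphi, kp) {
  V <- tryCatch(solve(hessian), error = function(e) NULL)
  one_block <- function(X, idx, label) {
    ux <- unique(as.data.frame(X))
    Xu <- as.matrix(ux)
    eta <- drop(Xu %*% beta[idx])
    est <- plogis(eta)
    se_r <- rep(NA_real_, length(eta))
    if (!is.null(V)) {
      for (i in seq_along(eta)) {
        g <- est[i] * (1 - est[i]) * Xu[i, ]
        se_r[i] <- sqrt(drop(t(g) %*% V[idx, idx, drop = FALSE] %*% g))
      }
    }
    data.frame(parameter = label,
               design = apply(ux, 1L, function(r)
                 paste(colnames(Xu), r, sep = "=", collapse = ",")),
               estimate = est, se = se_r, stringsAsFactors = FALSE)
  }
  rbind(one_block(Xphi, seq_len(kphi), "phi"),
        one_block(Xp, kphi + seq_len(kp), "p"))
}

#' @export
print.cjs_fit <- function(x, ...) {
  cat(x$model, " logLik =", round(x$logLik, 3), " K =", x$K,
      " AICc =", round(x$AICc, 2),
      if (!x$converged) " [NOT CONVERGED]",
      if (x$boundary) " [boundary]", "\n")
  print(data.frame(beta = round(x$beta, 4), se = round(x$se, 4)))
  invisible(x)
}

#' Small-sample Akaike information criterion
#'
#' `AICc = -2 logLik + 2K + 2K(K+1)/(ess - K - 1)`.
#'
#' @param logLik maximized log-likelihood.
#' @param K number of free parameters.
#' @param ess effective sample size (> K + 1).
#' @return numeric AICc.
#' @export
aicc <- function(logLik, K, ess) {
  if (ess <= K + 1) stop("effective sample size must exceed K + 1",
                         call. = FALSE)
  -2 * logLik + 2 * K + 2 * K * (K + 1) / (ess - K - 1)
}

rank_models <- function(fits) {
  ok <- vapply(fits, function(f) f$converged, logical(1))
  if (!all(ok)) warning(sum(!ok), " non-convergent model(s) excluded")
  fits <- fits[ok]
  tab <- data.frame(Model = vapply(fits, `[[`, character(1), "model"),
                    Npar = vapply(fits, `[[`, numeric(1), "K"),
                    AICc = vapply(fits, `[[`, numeric(1), "AICc"),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$AICc), , drop = FALSE]
  tab$dAICc <- tab$AICc - tab$AICc[1L]
  w <- exp(-tab$dAICc / 2)
  tab$Weight <- w / sum(w)
  tab$strong_support <- tab$dAICc < 2
  rownames(tab) <- NULL
  list(table = tab, fits = fits[order(vapply(fits, `[[`, numeric(1),
                                             "AICc"))])
}

#' Two-step AICc model selection for CJS models
#'
#' Step 1 screens detection structures while survival carries all three
#' covariates: `Phi(~season+sex+adult)` crossed with
#' `p in {~1, ~adult, ~sex, ~season}`, plus the full null
#' `Phi(~1)p(~1)`.  Step 2 fixes detection at the step-1 winner's formula
#' and screens `Phi in {~1, ~adult, ~sex, ~season}`, again with the full
#' null for completeness.  Tables carry Npar, AICc, delta-AICc and Akaike
#' weights; models with delta-AICc < 2 are flagged as strongly supported.
#'
#' @param histories an [encounter_histories()] object.
#' @param p_candidates,phi_candidates,phi_step1 candidate formula sets.
#' @return list with `step1`, `step2` (ranked tables), `p_winner`,
#'   `best_fit` (the step-2 top model's `"cjs_fit"`).
#' @export
model_selection_two_step <- function(histories,
                                     p_candidates = list(~1, ~adult, ~sex,
                                                         ~season),
                                     phi_candidates = list(~1, ~adult,
                                                           ~sex, ~season),
                                     phi_step1 = ~season + sex + adult) {
  fits1 <- lapply(p_candidates, function(pf)
    fit_cjs(histories, phi_step1, pf))
  fits1 <- c(fits1, list(fit_cjs(histories, ~1, ~1)))
  s1 <- rank_models(fits1)
  p_winner <- s1$fits[[1L]]$p_formula
  fits2 <- lapply(phi_candidates, function(ff)
    fit_cjs(histories, ff, p_winner))
  if (!any(vapply(fits2, function(f)
        f$model == model_label(~1, ~1), logical(1))) &&
      model_label(~1, ~1) != model_label(~1, p_winner))
    fits2 <- c(fits2, list(fit_cjs(histories, ~1, ~1)))
  s2 <- rank_models(fits2)
  list(step1 = s1$table, step2 = s2$table, p_winner = p_winner,
       best_fit = s2$fits[[1L]])
}

#' Convert monthly apparent survival to the annual scale
#'
#' @param phi_monthly monthly survival probability in `[0, 1]`.
#' @return `phi_monthly^12`.
#' @export
annual_survival <- function(phi_monthly) {
  if (any(phi_monthly < 0 | phi_monthly > 1))
    stop("monthly survival must lie in [0, 1]", call. = FALSE)
  phi_monthly^12
}
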