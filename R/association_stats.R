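#' Genotype-phenotype association tests
#'
#' Links genomic features of the evolved populations (variant
#' frequencies, copy numbers, HGT frequencies, window statistics) to
#' phenotypes and to the experimental design: coverage-weighted linear
#' regression against a phenotype, nested ANOVA over the
#' transfer/treatment design with replicate blocked within treatment,
#' Spearman rank correlation, Benjamini-Hochberg FDR correction, and
#' the four candidate-region criteria.
#'
#' @name association_stats
NULL

#' Weighted least-squares regression
#'
#' Fits `y ~ x` with observation weights (typically log10 coverage, or
#' inverse variance). Thin wrapper around [stats::lm()] exposing the
#' slope test directly.
#'
#' @param data Data frame.
#' @param x,y Column names (strings) or bare names of predictor and
#'   response.
#' @param weights Optional column of positive weights; `NULL` fits
#'   ordinary least squares.
#' @return Object of class `wls_fit` wrapping the `lm` fit; see
#'   [tidy.wls_fit()] and [glance.wls_fit()].
#' @export
weighted_least_squares <- function(data, x, y, weights = NULL) {
  x <- rlang::as_name(rlang::ensym(x))
  y <- rlang::as_name(rlang::ensym(y))
  w_quo <- rlang::enquo(weights)
  check_columns(data, c(x, y), "data")
  if (nrow(data) < 3) abort("need at least 3 points")
  w <- if (rlang::quo_is_null(w_quo)) {
    rep(1, nrow(data))
  } else {
    rlang::eval_tidy(w_quo, data)
  }
  if (any(w <= 0)) abort("weights must be positive")
  df <- data.frame(.y = data[[y]], .x = data[[x]], .w = w)
  fit <- lm(.y ~ .x, data = df, weights = .w)
  if (any(!is.finite(stats::coef(fit)))) {
    abort("singular design: x has no variation")
  }
  structure(list(fit = fit, x = x, y = y), class = "wls_fit")
}

#' @export
print.wls_fit <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  cat(sprintf("<wls_fit> %s ~ %s: slope %.4g (p = %.3g), R^2 %.3f\n",
              x$y, x$x, co[2, 1], co[2, 4], summary(x$fit)$r.squared))
  invisible(x)
}

#' @rdname weighted_least_squares
#' @param x A `wls_fit` object.
#' @param ... Unused.
#' @export
tidy.wls_fit <- function(x, ...) {
  co <- suppressWarnings(summary(x$fit))$coefficients
  tibble(term = c("intercept", "slope"),
         estimate = unname(co[, 1]), std.error = unname(co[, 2]),
         statistic = unname(co[, 3]), p.value = unname(co[, 4]))
}

#' @rdname weighted_least_squares
#' @export
glance.wls_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))
  tibble(r.squared = s$r.squared,
         sigma = s$sigma,
         statistic = unname(s$coefficients[2, 3]),
         p.value = unname(s$coefficients[2, 4]),
         df.residual = x$fit$df.residual,
         nobs = stats::nobs(x$fit))
}

#' Nested ANOVA over the transfer/treatment design
#'
#' Fixed-effects linear model `value ~ transfer + treatment +
#' treatment:replicate + transfer:treatment`, with replicate blocked
#' within treatment, Type-II sums of squares, and F-tests against the
#' residual mean square. Inestimable terms (empty cells) are reported
#' with `NA`.
#'
#' @param data Data frame with one row per population sample.
#' @param value,transfer,treatment,replicate Column names (strings or
#'   bare names).
#' @return Object of class `nested_anova`; [tidy.nested_anova()] gives
#'   the term table.
#' @export
nested_anova <- function(data, value, transfer, treatment, replicate) {
  cols <- vapply(rlang::ensyms(value, transfer, treatment, replicate),
                 rlang::as_name, character(1))
  check_columns(data, cols, "data")
  df <- data.frame(value = data[[cols[1]]],
                   transfer = factor(data[[cols[2]]]),
                   treatment = factor(data[[cols[3]]]),
                   replicate = factor(data[[cols[4]]]))
  for (f in c("transfer", "treatment")) {
    if (nlevels(df[[f]]) < 2) abort(sprintf("`%s` needs >= 2 levels", f))
  }
  fit <- lm(value ~ transfer + treatment + treatment:replicate +
              transfer:treatment, data = df)
  tab <- tryCatch(
    car::Anova(fit, type = 2, singular.ok = TRUE),
    error = function(e) {
      if (!grepl("residual sum of squares is 0", conditionMessage(e))) {
        stop(e)
      }
      # noise-free data: report term SS directly; a term with zero SS
      # contributes nothing (F = 0), any nonzero SS is infinitely
      # significant against a zero residual
      a1 <- suppressWarnings(stats::anova(fit))
      ss <- a1[["Sum Sq"]]
      zero <- ss < .Machine$double.eps * 100
      a1[["F value"]] <- ifelse(zero, 0, Inf)
      a1[["Pr(>F)"]] <- ifelse(zero, 1, 0)
      a1[["F value"]][rownames(a1) == "Residuals"] <- NA
      a1[["Pr(>F)"]][rownames(a1) == "Residuals"] <- NA
      a1
    })
  structure(list(fit = fit, anova = tab), class = "nested_anova")
}

#' @export
print.nested_anova <- function(x, ...) {
  print(x$anova)
  invisible(x)
}

#' @rdname nested_anova
#' @param x A `nested_anova` object.
#' @param ... Unused.
#' @export
tidy.nested_anova <- function(x, ...) {
  tab <- as.data.frame(x$anova)
  tibble(term = rownames(tab),
         sumsq = tab[["Sum Sq"]],
         df = tab[["Df"]],
         statistic = tab[["F value"]],
         p.value = tab[["Pr(>F)"]])
}

#' @rdname nested_anova
#' @export
glance.nested_anova <- function(x, ...) {
  s <- summary(x$fit)
  tibble(r.squared = s$r.squared, sigma = s$sigma,
         df.residual = x$fit$df.residual, nobs = stats::nobs(x$fit))
}

# all permutations of 1..n as a matrix (n! rows); n <= 9 in practice
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Pearson correlation of fractional ranks. For n < 10 with untied data
#' the two-sided p-value is computed by full enumeration of all n!
#' permutations (`P(|rho_perm| >= |rho_obs|)`); otherwise the t
#' approximation on n - 2 degrees of freedom is used.
#'
#' @param x,y Numeric vectors of equal length >= 4.
#' @return Tibble `rho`, `p.value`, `method`.
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) abort("need at least 4 complete pairs")
  if (var(x) == 0 || var(y) == 0) {
    abort("undefined correlation: constant vector")
  }
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  ties <- anyDuplicated(rx) || anyDuplicated(ry)
  if (n < 10 && !ties) {
    perms <- all_perms(n)
    rho_all <- apply(perms, 1, function(pm) cor(rx, ry[pm]))
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
    tibble(rho = rho, p.value = p, method = "exact permutation")
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), n - 2)
    tibble(rho = rho, p.value = min(p, 1), method = "t approximation")
  }
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: `q_i = min over j >= rank(i) of m p_(j) / j`,
#' capped at 1; stable under input order. Delegates to
#' [stats::p.adjust()] after validation.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values in the input order.
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p) || any(!is.na(p) & (p < 0 | p > 1))) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Candidate-region criteria
#'
#' Flags genomic features that (i) vary in at least `min_replicates`
#' replicate populations, (ii) show a treatment effect
#' (q < `alpha`) but neither a transfer nor an interaction effect
#' (both q >= `alpha`), (iii) for HGT features, pass the strict
#' treatment-variance screen (> `hgt_variance`), and (iv) have a
#' functional consequence (annotation passed through).
#'
#' @param results Tibble with columns `feature`,
#'   `n_replicates_with_variation`, `q_treatment`, `q_transfer`,
#'   `q_interaction`; optionally `is_hgt`, `treatment_variance`,
#'   `functional_consequence`.
#' @param min_replicates Criterion (i) threshold (default 4).
#' @param alpha FDR threshold for criterion (ii) (default 0.05).
#' @param hgt_variance Criterion (iii) threshold (default 0.04).
#' @return `results` with a logical `candidate` column added.
#' @export
candidate_region_filter <- function(results, min_replicates = 4,
                                    alpha = 0.05, hgt_variance = 0.04) {
  check_columns(results, c("feature", "n_replicates_with_variation",
                           "q_treatment", "q_transfer", "q_interaction"),
                "results")
  r <- as_tibble(results)
  if (!"is_hgt" %in% names(r)) r$is_hgt <- FALSE
  if (!"treatment_variance" %in% names(r)) r$treatment_variance <- NA_real_
  if (!"functional_consequence" %in% names(r)) {
    r$functional_consequence <- TRUE
  }
  r$candidate <-
    r$n_replicates_with_variation >= min_replicates &
    !is.na(r$q_treatment) & r$q_treatment < alpha &
    (is.na(r$q_transfer) | r$q_transfer >= alpha) &
    (is.na(r$q_interaction) | r$q_interaction >= alpha) &
    (!r$is_hgt | (!is.na(r$treatment_variance) &
                    r$treatment_variance > hgt_variance)) &
    r$functional_consequence
  r
}

#' Run the association battery over a feature table
#'
#' For every feature column: a weighted regression against the
#' phenotype and a nested ANOVA over the design, with
#' Benjamini-Hochberg correction applied across features within each
#' test family.
#'
#' @param features Tibble with one row per (replicate, transfer)
#'   population: design columns `treatment`, `transfer`, `replicate`, a
#'   phenotype column, optionally a weight column, plus feature columns.
#' @param feature_cols Character vector of feature column names.
#' @param phenotype Name of the phenotype column.
#' @param weight_col Optional name of the regression weight column
#'   (e.g. log10 coverage).
#' @param blacklist Optional tibble `treatment`, `transfer`, `replicate`
#'   of population samples to exclude before testing.
#' @return Tibble (class `association_results`): `feature`, `test`,
#'   `statistic`, `p.value`, `q.value`, `n_replicates_with_variation`.
#' @export
associate_features <- function(features, feature_cols, phenotype,
                               weight_col = NULL, blacklist = NULL) {
  check_columns(features, c("treatment", "transfer", "replicate",
                            phenotype, feature_cols), "features")
  dat <- as_tibble(features)
  if (!is.null(blacklist)) {
    check_columns(blacklist, c("treatment", "transfer", "replicate"),
                  "blacklist")
    dat <- anti_join(dat, blacklist,
                     by = c("treatment", "transfer", "replicate"))
  }
  res <- purrr::map_dfr(feature_cols, function(fc) {
    # a replicate lineage "shows variation" when the feature deviates
    # from its across-population median in any of its transfers
    med <- median(dat[[fc]], na.rm = TRUE)
    nvar <- dat %>%
      group_by(.data$treatment, .data$replicate) %>%
      summarise(v = any(.data[[fc]] != med, na.rm = TRUE),
                .groups = "drop") %>%
      summarise(n = sum(.data$v)) %>%
      dplyr::pull(n)
    wls <- tryCatch({
      f <- weighted_least_squares(
        dat, x = !!rlang::sym(fc), y = !!rlang::sym(phenotype),
        weights = if (!is.null(weight_col)) dat[[weight_col]])
      glance.wls_fit(f)
    }, error = function(e) tibble(statistic = NA_real_, p.value = NA_real_))
    an <- tryCatch({
      a <- tidy.nested_anova(
        nested_anova(dat, value = !!rlang::sym(fc), transfer = transfer,
                     treatment = treatment, replicate = replicate))
      a
    }, error = function(e) NULL)
    pick <- function(term) {
      if (is.null(an) || !term %in% an$term) {
        c(NA_real_, NA_real_)
      } else {
        c(an$statistic[an$term == term], an$p.value[an$term == term])
      }
    }
    tr <- pick("treatment"); tf <- pick("transfer")
    ia <- pick("transfer:treatment")
    tibble(feature = fc,
           test = c("wls", "anova-treatment", "anova-transfer",
                    "anova-interaction"),
           statistic = c(wls$statistic[1], tr[1], tf[1], ia[1]),
           p.value = c(wls$p.value[1], tr[2], tf[2], ia[2]),
           n_replicates_with_variation = nvar)
  })
  res <- res %>%
    group_by(.data$test) %>%
    mutate(q.value = bh_fdr(.data$p.value)) %>%
    ungroup()
  structure(res, class = c("association_results", class(res)))
}
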