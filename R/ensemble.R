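#' Multi-model ensemble set
#'
#' Bundles one gridded field per climate model with weights (equal `1/N` by
#' default, the standard model-democracy convention). Members may be
#' `gdd_field`s or bare matrices; all must share grid (and label year when
#' present).
#'
#' @param member_fields list of same-typed fields.
#' @param model_ids character labels, one per member.
#' @param weights numeric weights summing to 1; default equal.
#' @return object of class `ensemble_set`.
#' @export
ensemble_set <- function(member_fields, model_ids = NULL, weights = NULL) {
  n <- length(member_fields)
  if (n < 1) stop("ensemble needs at least one member")
  if (is.null(model_ids)) model_ids <- sprintf("model_%02d", seq_len(n))
  if (is.null(weights)) weights <- rep(1 / n, n)
  if (length(weights) != n) stop("one weight per member required")
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  g <- member_grid(member_fields[[1]])
  for (f in member_fields[-1]) {
    if (!is.null(g) && !is.null(member_grid(f)) && !same_grid(g, member_grid(f)))
      stop("all ensemble members must share a grid")
  }
  structure(list(member_fields = member_fields, model_ids = model_ids,
                 weights = weights),
            class = "ensemble_set")
}

member_grid <- function(f) if (is.matrix(f)) NULL else f$grid

member_values <- function(f) {
  if (is.matrix(f)) return(f)
  if (inherits(f, "gdd_field")) return(f$gdd)
  if (inherits(f, "feas_mask")) return(f$feasible + 0)
  stop("unsupported ensemble member type")
}

ens_array <- function(ens) {
  vs <- lapply(ens$member_fields, member_values)
  array(unlist(vs), c(dim(vs[[1]]), length(vs)))
}

#' Equal-weight ensemble mean
#'
#' Cellwise weighted mean across members. Under the default strict missing
#' policy a cell missing in any member is missing in the mean (so the model
#' count never varies by cell); `na_policy = "available"` renormalizes over
#' the non-missing members instead.
#'
#' @param ens an `ensemble_set`.
#' @param na_policy `"strict"` or `"available"`.
#' @return matrix of cellwise means.
#' @export
ensemble_mean <- function(ens, na_policy = c("strict", "available")) {
  na_policy <- match.arg(na_policy)
  a <- ens_array(ens)
  w <- ens$weights
  if (na_policy == "strict") {
    out <- 0
    for (k in seq_along(w)) out <- out + w[k] * a[, , k]
    out
  } else {
    num <- den <- array(0, dim(a)[1:2])
    for (k in seq_along(w)) {
      ok <- !is.na(a[, , k])
      num[ok] <- num[ok] + w[k] * a[, , k][ok]
      den[ok] <- den[ok] + w[k]
    }
    ifelse(den > 0, num / den, NA_real_)
  }
}

#' Cellwise ensemble min and max
#'
#' @param ens an `ensemble_set`.
#' @return list with matrices `min` and `max` (strict missing policy).
#' @export
ensemble_range <- function(ens) {
  a <- ens_array(ens)
  list(min = apply(a, c(1, 2), min), max = apply(a, c(1, 2), max))
}

#' Cellwise inter-model coefficient of variation
#'
#' Sample standard deviation (n-1 denominator; an ensemble of 7 is a small
#' sample) divided by the ensemble mean; missing where the mean is zero.
#'
#' @param ens an `ensemble_set` with at least two members.
#' @return matrix of CV values.
#' @export
ensemble_cv <- function(ens) {
  if (length(ens$member_fields) < 2)
    stop("ensemble_cv needs at least two members")
  a <- ens_array(ens)
  m <- apply(a, c(1, 2), mean)
  s <- apply(a, c(1, 2), stats::sd)
  ifelse(!is.na(m) & m != 0, s / m, NA_real_)
}

#' Scenario period summary
#'
#' @param scenario label, e.g. `"emission"` or `"transient"`.
#' @param period_labels character labels for the periods.
#' @param values one summary number per period (e.g. global feasible area).
#' @return object of class `scenario_summary`.
#' @export
scenario_summary <- function(scenario, period_labels, values) {
  if (length(period_labels) != length(values))
    stop("one value per period label required")
  structure(list(scenario = scenario, period_labels = period_labels,
                 values = as.numeric(values)),
            class = "scenario_summary")
}

#' Compare two scenario summaries (variance-ratio F and Student t)
#'
#' Two-sided variance-ratio F test on the two period-value samples and a
#' pooled-variance two-sample Student t test on their means - the classical
#' pairing used to ask whether emission-based and transient-GHG scenario
#' runs are statistically similar. (The "Fisher test" is read as the
#' variance F test; see the methods vignette.)
#'
#' @param a,b `scenario_summary` objects with equal period counts >= 2 and
#'   aligned period labels.
#' @return list with `f_statistic`, `f_p_value`, `t_statistic`, `t_p_value`,
#'   `df`, and logical `degenerate` (TRUE when both samples have zero
#'   variance so t is undefined).
#' @export
compare_scenarios <- function(a, b) {
  if (length(a$values) != length(b$values) || length(a$values) < 2)
    stop("scenario summaries need equal period counts >= 2")
  if (!identical(a$period_labels, b$period_labels))
    stop("period labels are not aligned between scenarios")
  x <- a$values; y <- b$values
  n1 <- length(x); n2 <- length(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (v1 == 0 && v2 == 0) {
    f <- if (identical(x, y)) 1 else NaN
    return(list(f_statistic = f, f_p_value = if (is.nan(f)) NA_real_ else 1,
                t_statistic = NA_real_, t_p_value = NA_real_,
                df = n1 + n2 - 2L, degenerate = TRUE))
  }
  f <- v1 / v2
  pf_low <- stats::pf(f, n1 - 1, n2 - 1)
  f_p <- min(1, 2 * min(pf_low, 1 - pf_low))
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  t_p <- 2 * stats::pt(-abs(tt), df = n1 + n2 - 2)
  list(f_statistic = f, f_p_value = f_p,
       t_statistic = tt, t_p_value = t_p,
       df = n1 + n2 - 2L, degenerate = FALSE)
}
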