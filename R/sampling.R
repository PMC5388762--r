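#' Initial-condition bounds table
#'
#' The packaged per-metabolite lower/upper concentration bounds (mM) used to
#' sample initial conditions: literature ranges across cancer cell lines and
#' patient samples, widened by 20% for pancreatic-cancer uncertainty.
#'
#' @return data.frame with columns `metabolite`, `lower`, `upper`.
#' @export
ic_bounds <- function() {
  b <- utils::read.csv(system.file("extdata", "ic_bounds.csv",
                                   package = "pdacmet"))
  if (any(b$lower <= 0) || any(b$lower > b$upper))
    stop("invalid bounds table")
  b
}

#' Validated initial conditions
#'
#' The two initial-condition sets that survive training and validation
#' against cell-proliferation data; IC #1 is the reference baseline.
#'
#' @return data.frame with columns `metabolite`, `ic1`, `ic2`.
#' @export
validated_ic <- function() {
  utils::read.csv(system.file("extdata", "validated_ic.csv",
                              package = "pdacmet"))
}

#' Latin hypercube sampling of initial conditions
#'
#' Stratified sampling: for every metabolite the concentration range is split
#' into `n` equal-width strata and each stratum is sampled exactly once
#' (uniformly within the stratum), giving uniform marginal coverage.
#' Metabolites present in both compartments (the `lhs_copy_of` pairs of the
#' model configuration, e.g. MAL/mMAL) receive identical values, since
#' measurements do not resolve compartments.
#'
#' @param bounds data.frame as from [ic_bounds()] (columns `metabolite`,
#'   `lower`, `upper`).
#' @param n number of initial-condition sets (>= 1).
#' @param seed integer seed; recorded in the result's attributes.
#' @param copy_map named character vector mapping duplicate metabolites to
#'   their sampled source (default: the reference model's compartment
#'   duplicates). Entries absent from `bounds` rows are added as copies.
#' @return matrix `n` x metabolites (named columns), attribute `seed`.
#' @export
lhs_initial_conditions <- function(bounds, n, seed = 1,
                                   copy_map = c(mPYR = "PYR", mCIT = "CIT",
                                                mAKG = "AKG", mMAL = "MAL",
                                                mOAA = "OAA", mASP = "ASP",
                                                mGLU = "GLU")) {
  if (n < 1) stop("n must be >= 1")
  if (any(bounds$lower <= 0) || any(bounds$lower > bounds$upper))
    stop("invalid bounds: need 0 < lower <= upper")
  copy_map <- copy_map[names(copy_map) %in% bounds$metabolite]
  base <- bounds[!bounds$metabolite %in% names(copy_map), ]
  set.seed(seed)
  u <- lhs::randomLHS(n, nrow(base))
  x <- sweep(sweep(u, 2, base$upper - base$lower, `*`), 2, base$lower, `+`)
  colnames(x) <- base$metabolite
  out <- matrix(NA_real_, n, nrow(bounds),
                dimnames = list(NULL, bounds$metabolite))
  out[, base$metabolite] <- x
  for (dup in names(copy_map)) out[, dup] <- out[, copy_map[[dup]]]
  attr(out, "seed") <- seed
  out
}

#' Gaussian Monte Carlo initial conditions around a baseline
#'
#' Each metabolite is drawn from a Gaussian with mean equal to the baseline
#' value and standard deviation `sd_scale` times the mean (default 1/6),
#' truncated to +/- 50% of the baseline so all draws lie within three
#' standard deviations of the mean.
#'
#' @param baseline named numeric vector of strictly positive concentrations.
#' @param n number of draws.
#' @param seed integer seed.
#' @param sd_scale standard deviation as a fraction of the mean; 0 gives
#'   degenerate (all-equal-to-baseline) draws.
#' @param rel_width truncation half-width as a fraction of the mean.
#' @return matrix `n` x metabolites, attribute `seed`.
#' @export
gaussian_initial_conditions <- function(baseline, n, seed = 1,
                                        sd_scale = 1 / 6, rel_width = 0.5) {
  if (any(baseline <= 0)) stop("baseline must be strictly positive: ",
    paste(names(baseline)[baseline <= 0], collapse = ", "))
  set.seed(seed)
  out <- matrix(NA_real_, n, length(baseline),
                dimnames = list(NULL, names(baseline)))
  for (j in seq_along(baseline)) {
    mu <- baseline[[j]]
    if (sd_scale == 0) { out[, j] <- mu; next }
    sd <- sd_scale * mu
    a <- stats::pnorm((1 - rel_width) * mu, mu, sd)
    b <- stats::pnorm((1 + rel_width) * mu, mu, sd)
    out[, j] <- stats::qnorm(a + stats::runif(n) * (b - a), mu, sd)
  }
  attr(out, "seed") <- seed
  out
}

#' Write an initial-condition ensemble with provenance sidecar
#'
#' @param ens matrix from [lhs_initial_conditions()] or
#'   [gaussian_initial_conditions()].
#' @param path output CSV path; a `<path>.meta.json` sidecar records the
#'   seed and generation call.
#' @param meta extra provenance fields (named list).
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ens, path, meta = list()) {
  utils::write.csv(as.data.frame(ens), path, row.names = FALSE)
  meta <- c(list(seed = attr(ens, "seed"), n = nrow(ens),
                 metabolites = colnames(ens),
                 created = format(Sys.time(), tz = "UTC")), meta)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}
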