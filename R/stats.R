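#' Percent change of a treated group relative to control
#'
#' `100 * (treated_mean - control_mean) / control_mean`, the signed percent
#' scale on which group effects are reported (e.g. a fascicle abundance
#' falling to less than one third of control is a change of -73.3%).
#'
#' @param control_mean control group mean, strictly positive.
#' @param treated_mean treated group mean, non-negative.
#' @return Signed percent change.
#' @export
percent_change <- function(control_mean, treated_mean) {
  if (!is.finite(control_mean) || control_mean <= 0)
    stop("control_mean must be strictly positive", call. = FALSE)
  if (any(treated_mean < 0))
    stop("treated_mean must be non-negative", call. = FALSE)
  100 * (treated_mean - control_mean) / control_mean
}

#' Build a table of per-animal records
#'
#' @param animal animal identifiers.
#' @param group `"control"` or `"treated"` per animal.
#' @param value the measured statistic (a count or unit total) per animal.
#' @param batch day-of-preparation label per animal; permutations are
#'   stratified within batches.
#' @param sex optional sex label.
#' @return A data frame of class `animal_records`.
#' @export
animal_records <- function(animal, group, value, batch, sex = NULL) {
  stopifnot(length(group) == length(animal), length(value) == length(animal),
            length(batch) == length(animal))
  if (!all(group %in% c("control", "treated")))
    stop("group must be 'control' or 'treated'", call. = FALSE)
  if (any(value < 0)) stop("values must be non-negative", call. = FALSE)
  if (any(is.na(batch))) stop("batch must be present for every record",
                              call. = FALSE)
  df <- data.frame(animal = animal, group = group, value = as.numeric(value),
                   batch = as.character(batch))
  if (!is.null(sex)) df$sex <- sex
  class(df) <- c("animal_records", class(df))
  df
}

# all within-stratum group relabelings, as a list of treated-index sets
enumerate_assignments <- function(strata_idx, strata_k) {
  per_stratum <- Map(function(idx, k) {
    utils::combn(idx, k, simplify = FALSE)
  }, strata_idx, strata_k)
  grids <- expand.grid(lapply(per_stratum, seq_along))
  lapply(seq_len(nrow(grids)), function(r)
    unlist(Map(function(opts, pick) opts[[pick]], per_stratum,
               as.integer(grids[r, ]))))
}

#' Batch-stratified permutation test for a two-group difference
#'
#' Tests the difference in group means with group labels permuted only
#' within day-of-preparation batches, so that batch-level shifts cannot
#' masquerade as treatment effects. When the number of admissible
#' relabelings is at most `exhaustive_limit` the null distribution is
#' enumerated exactly (p = fraction of relabelings with `|difference| >=`
#' observed, which includes the identity); otherwise `n_permutations`
#' seeded Monte Carlo draws are used with the add-one correction
#' `p = (1 + #{extreme}) / (1 + n_permutations)`. Batches containing only
#' one group carry no within-batch label information and are pooled into a
#' common stratum with a warning.
#'
#' @param records an [animal_records()] data frame (or compatible).
#' @param statistic name of the value column, default `"value"`.
#' @param n_permutations Monte Carlo draws when enumeration is infeasible.
#' @param seed integer seed for the Monte Carlo branch.
#' @param exhaustive_limit enumerate exactly when the admissible
#'   relabeling count does not exceed this.
#' @return List with `p_value`, `observed` (treated mean - control mean),
#'   `method` (`"exhaustive"` or `"monte_carlo"`), `n_permutations`.
#' @export
permutation_test <- function(records, statistic = "value",
                             n_permutations = 10000L, seed = 1L,
                             exhaustive_limit = 20000L) {
  g <- records$group
  v <- records[[statistic]]
  b <- as.character(records$batch)
  if (sum(g == "control") < 2 || sum(g == "treated") < 2)
    stop("need at least two animals per group", call. = FALSE)
  single <- names(which(vapply(split(g, b), function(x)
    length(unique(x)) == 1, logical(1))))
  if (length(single) > 0) {
    warning(sprintf(
      "batch(es) %s contain only one group; pooling them into one stratum",
      paste(single, collapse = ", ")), call. = FALSE)
    b[b %in% single] <- ".pooled"
  }
  strata <- split(seq_along(g), b)
  strata_k <- vapply(strata, function(idx) sum(g[idx] == "treated"),
                     integer(1))
  obs <- mean(v[g == "treated"]) - mean(v[g == "control"])
  n_tr <- sum(g == "treated")
  n_ct <- sum(g == "control")
  diff_for <- function(treated_idx) {
    s <- sum(v[treated_idx])
    s / n_tr - (sum(v) - s) / n_ct
  }
  n_admissible <- prod(vapply(seq_along(strata), function(i)
    choose(length(strata[[i]]), strata_k[i]), numeric(1)))
  tol <- 1e-9 * (abs(obs) + 1)
  if (n_admissible <= exhaustive_limit) {
    perms <- enumerate_assignments(strata, strata_k)
    diffs <- vapply(perms, diff_for, numeric(1))
    p <- mean(abs(diffs) >= abs(obs) - tol)
    method <- "exhaustive"
    n_used <- length(perms)
  } else {
    diffs <- with_seed(seed, vapply(seq_len(n_permutations), function(i) {
      treated_idx <- unlist(Map(function(idx, k)
        if (k == 0) integer(0) else idx[sample.int(length(idx), k)],
        strata, strata_k))
      diff_for(treated_idx)
    }, numeric(1)))
    p <- (1 + sum(abs(diffs) >= abs(obs) - tol)) / (1 + n_permutations)
    method <- "monte_carlo"
    n_used <- n_permutations
  }
  list(p_value = p, observed = obs, method = method,
       n_permutations = n_used)
}

#' Compare two groups on one endpoint
#'
#' Means, standard errors, percent change and stratified permutation
#' p-value for one measured statistic.
#'
#' @param records an [animal_records()] data frame.
#' @param name endpoint name carried into the output row.
#' @param statistic value column, default `"value"`.
#' @param seed,n_permutations passed to [permutation_test()].
#' @return One-row data frame (`statistic`, group means and SEs,
#'   `percent_change`, `p_value`, group sizes).
#' @export
compare_groups <- function(records, name = "value", statistic = "value",
                           seed = 1L, n_permutations = 10000L) {
  v <- records[[statistic]]
  g <- records$group
  se <- function(x) stats::sd(x) / sqrt(length(x))
  pt <- permutation_test(records, statistic, n_permutations, seed)
  data.frame(
    statistic = name,
    control_mean = mean(v[g == "control"]),
    control_se = se(v[g == "control"]),
    treated_mean = mean(v[g == "treated"]),
    treated_se = se(v[g == "treated"]),
    percent_change = percent_change(mean(v[g == "control"]),
                                    mean(v[g == "treated"])),
    p_value = pt$p_value,
    n_control = sum(g == "control"),
    n_treated = sum(g == "treated")
  )
}

#' Simulate per-animal abundance records under the study's variance model
#'
#' Draws per-animal structure abundances with multiplicative lognormal
#' biological variation and a shared multiplicative batch (day of
#' preparation) effect, then rounds to integer counts — the same abundance
#' model that scales the phantom generator in the replication study. Used
#' to calibrate the stratified permutation test (e.g. its null type-I
#' rate) at a cost that permits hundreds of repetitions.
#'
#' @param n_per_group animals per arm.
#' @param base_abundance control-arm mean abundance.
#' @param ratio treated/control abundance ratio (1 = null).
#' @param cv lognormal coefficient of variation of per-animal abundance.
#' @param batch_sd s.d. of the lognormal batch effect.
#' @param n_batches number of preparation days; animals are assigned in
#'   rotation so each batch holds both groups.
#' @param seed integer seed.
#' @return An [animal_records()] data frame.
#' @export
simulate_animal_records <- function(n_per_group = 6, base_abundance = 15,
                                    ratio = 1, cv = 0.08, batch_sd = 0.05,
                                    n_batches = 3, seed = 1L) {
  with_seed(seed, {
    n <- 2L * n_per_group
    group <- rep(c("control", "treated"), each = n_per_group)
    batch <- paste0("day", rep_len(seq_len(n_batches), n))
    bfx <- stats::setNames(exp(stats::rnorm(n_batches, 0, batch_sd)),
                           paste0("day", seq_len(n_batches)))
    mu <- base_abundance * ifelse(group == "treated", ratio, 1)
    value <- round(mu * bfx[batch] * exp(stats::rnorm(n, 0, cv)))
    animal_records(sprintf("m%02d", seq_len(n)), group, value, batch)
  })
}
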