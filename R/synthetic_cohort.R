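#' The 30 secondary-health-condition short labels
#'
#' Standard abbreviations for the 30 items of the full multimorbidity
#' instrument (autonomic dysreflexia, bowel incontinence, cancer,
#' constipation, osteoarthritis, depression, diabetes, DVT/PE, elbow/wrist
#' problems, fatigue, high blood pressure, heart disease, light-headedness,
#' injuries from loss of sensation, joint contractures, kidney stones,
#' liver disease, neurological deterioration, neuropathic pain,
#' osteoporosis, pressure ulcers, respiratory infections, sexual
#' dysfunction, shoulder problems, spasticity, trouble sleeping,
#' ulcer/GERD, urinary incontinence, urinary tract infection, weight
#' problem).
#'
#' @return Character vector of length 30.
#' @export
shc_labels <- function() {
  c("AD", "BI", "Can", "Cons", "DA", "Depre", "Dia", "DVT", "EP", "Fati",
    "HBP", "HD", "Head", "Inj", "JC", "KS", "LD", "ND", "NP", "Oste",
    "PU", "RI", "SD", "SP", "Spas", "TS", "Ulcer", "UI", "UTI", "WP")
}

#' Construct a planted truth network
#'
#' @param node_names Character labels, length `p`.
#' @param edges Data frame or list of `(i, j, weight)` triplets; indices may
#'   be integer positions or node names.
#' @param isolated Names of nodes that must carry no edges (checked).
#' @param fields Per-node intercepts for binary nodes (recycled scalar ok).
#' @param kinds Per-node `"binary"`/`"continuous"` (default all binary).
#' @return An object of class `truth_network` with elements `node_names`,
#'   `weights` (symmetric, zero diagonal), `fields`, `kinds`, `isolated`.
#' @export
make_truth_network <- function(node_names, edges = NULL,
                               isolated = character(0), fields = 0,
                               kinds = "binary") {
  p <- length(node_names)
  stopifnot(p >= 1, !anyDuplicated(node_names))
  w <- matrix(0, p, p, dimnames = list(node_names, node_names))
  if (!is.null(edges) && length(edges)) {
    if (!is.data.frame(edges))
      edges <- do.call(rbind.data.frame, lapply(edges, function(e)
        stats::setNames(as.data.frame(as.list(e)), c("i", "j", "weight"))))
    for (r in seq_len(nrow(edges))) {
      i <- edges[r, 1][[1]]; j <- edges[r, 2][[1]]
      wt <- as.numeric(edges[r, 3][[1]])
      if (is.character(i)) i <- match(i, node_names)
      if (is.character(j)) j <- match(j, node_names)
      i <- as.integer(i); j <- as.integer(j)
      if (is.na(i) || is.na(j) || i < 1 || j < 1 || i > p || j > p || i == j)
        stop("invalid edge indices at row ", r, call. = FALSE)
      if (node_names[i] %in% isolated || node_names[j] %in% isolated)
        stop("edge (", node_names[i], ", ", node_names[j],
             ") touches an isolated node", call. = FALSE)
      w[i, j] <- wt; w[j, i] <- wt
    }
  }
  fields <- rep_len(as.numeric(fields), p)
  kinds <- rep_len(kinds, p)
  structure(list(node_names = node_names, weights = w, fields = fields,
                 kinds = kinds, isolated = isolated),
            class = "truth_network")
}

#' @export
print.truth_network <- function(x, ...) {
  ne <- sum(x$weights[upper.tri(x$weights)] != 0)
  cat("<truth_network>", length(x$node_names), "nodes,", ne, "edges,",
      length(x$isolated), "planted isolated\n")
  invisible(x)
}

#' Sample multivariate Gaussian data with a given partial-correlation network
#'
#' Builds the unit-diagonal precision matrix `K` with `K[i,j] = -w[i,j]`
#' (so that the model's partial correlation matrix equals the truth
#' weights), inverts it to a covariance, and draws `n` zero-mean rows.
#'
#' @param truth A `truth_network` whose weights are partial correlations.
#' @param n Number of rows.
#' @param seed Integer seed.
#' @return Numeric matrix `n x p` with node-name columns.
#' @export
sample_gaussian <- function(truth, n, seed = 1L) {
  p <- length(truth$node_names)
  K <- diag(p) - truth$weights
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop("implied precision matrix is not positive definite ",
         "(smallest eigenvalue ", signif(min(ev), 4), ")", call. = FALSE)
  sigma <- solve(K)
  set.seed(seed)
  z <- matrix(stats::rnorm(n * p), n, p)
  x <- z %*% chol(sigma)
  colnames(x) <- truth$node_names
  x
}

#' Sample binary data from a 0/1 Ising model by Gibbs sampling
#'
#' Node conditionals are logistic: `P(x_i = 1 | rest) =
#' plogis(field_i + sum_j w_ij x_j)`. A single chain is run for
#' `burn_in + n * thin` full sweeps and every `thin`-th state is kept.
#'
#' @param truth A `truth_network` with all-binary kinds.
#' @param n Number of retained draws.
#' @param burn_in Discarded initial sweeps.
#' @param thin Keep one state per `thin` sweeps.
#' @param seed Integer seed.
#' @return Integer 0/1 matrix `n x p` with node-name columns.
#' @export
sample_ising_gibbs <- function(truth, n, burn_in = 200L, thin = 5L,
                               seed = 1L) {
  if (any(truth$kinds != "binary"))
    stop("Ising sampling requires all-binary nodes; non-binary: ",
         paste(truth$node_names[truth$kinds != "binary"], collapse = ", "),
         call. = FALSE)
  stopifnot(burn_in >= 0, thin >= 1, n >= 1)
  set.seed(seed)
  x <- .ising_gibbs_cpp(truth$weights, truth$fields, as.integer(n),
                        as.integer(burn_in), as.integer(thin))
  colnames(x) <- truth$node_names
  x
}

#' Default planted SHC truth network
#'
#' Mirrors the qualitative structure of multimorbidity networks in
#' spinal-cord-injury cohorts: five isolated comorbidity items (cancer,
#' DVT, diabetes, high blood pressure, liver disease), an autonomic
#' dysreflexia hub with seven edges, a strong elbow/wrist-shoulder pair,
#' and moderate positive couplings among the remaining items. Fields are
#' set by a mean-field correction to keep item prevalences near 0.35.
#'
#' @param hub_weight Coupling on each hub edge.
#' @param pair_weight Coupling of the strong elbow/wrist-shoulder pair.
#' @return A `truth_network` over [shc_labels()].
#' @export
default_shc_truth <- function(hub_weight = 0.8, pair_weight = 1.8) {
  iso <- c("Can", "DVT", "Dia", "HBP", "LD")
  hub <- c("Head", "Spas", "UTI", "PU", "BI", "UI", "Cons")
  edges <- rbind(
    data.frame(i = "AD", j = hub, weight = hub_weight),
    data.frame(i = "EP", j = "SP", weight = pair_weight),
    data.frame(i = c("Depre", "Depre", "Fati", "NP", "NP", "DA", "DA",
                     "JC", "KS", "RI", "PU", "Ulcer", "HD", "Oste",
                     "SD", "WP", "ND", "UI"),
               j = c("Fati", "TS", "Head", "TS", "Spas", "SP", "JC",
                     "Spas", "UTI", "UTI", "Inj", "Cons", "Fati", "DA",
                     "Depre", "Fati", "Spas", "UTI"),
               weight = 0.6))
  tn <- make_truth_network(shc_labels(), edges, isolated = iso)
  tn$fields <- stats::qlogis(0.35) - 0.4 * rowSums(tn$weights)
  tn
}

#' Configuration for a synthetic survey cohort
#'
#' @param n Number of participants (at least 10).
#' @param truth SHC truth network; defaults to [default_shc_truth()].
#' @param outcome_effect Magnitude of the total-SHC-count effect on each
#'   outcome's linear predictor, on the logit scale per condition; 0 severs
#'   every SHC-to-outcome link (including the planted depression effect on
#'   the mental score). The default matches the reported per-condition
#'   logistic coefficient of the full index on unmet-care-need (0.174).
#' @param count_center Centering constant for the SHC count in outcome
#'   linear predictors.
#' @param fncnr_prev Baseline prevalence of the unmet-care-need outcome at
#'   the centered count.
#' @param noise_pcs,noise_mcs Residual SDs of the physical/mental scores.
#' @param qol_cut Dichotomization cut for the 5-point QoL item.
#' @param seed Integer seed; fixing it makes the cohort fully reproducible.
#' @param cohort_label Cohort tag.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n = 1500L, truth = default_shc_truth(),
                          outcome_effect = 0.174, count_center = 10,
                          fncnr_prev = 0.25, noise_pcs = 7, noise_mcs = 8,
                          qol_cut = 4L, seed = 1L, cohort_label = "synthetic") {
  stopifnot(inherits(truth, "truth_network"))
  if (n < 10) stop("n must be at least 10", call. = FALSE)
  structure(list(n = as.integer(n), truth = truth,
                 isolated_items = truth$isolated,
                 hub_item = "AD",
                 outcome_effect = outcome_effect,
                 count_center = count_center, fncnr_prev = fncnr_prev,
                 noise_pcs = noise_pcs, noise_mcs = noise_mcs,
                 qol_cut = as.integer(qol_cut), seed = as.integer(seed),
                 cohort_label = cohort_label),
            class = "cohort_config")
}

#' Default variable metadata for the 30-item instrument and its outcomes
#'
#' The 30 binary SHC items, the five health outcomes (unmet care need,
#' physical and mental component scores, satisfaction and QoL ratings),
#' and the standard covariates.
#'
#' @return A spec data frame as from [survey_specs()].
#' @export
default_survey_specs <- function() {
  survey_specs(
    do.call(rbind, lapply(shc_labels(), variable_spec,
                          kind = "binary", role = "shc")),
    variable_spec("FNCNR", "binary", "outcome"),
    variable_spec("PCS", "continuous", "outcome"),
    variable_spec("MCS", "continuous", "outcome"),
    variable_spec("LiSAT", "ordinal", "outcome", levels = 1:6),
    variable_spec("QoL", "ordinal", "outcome", levels = 1:5),
    variable_spec("Age", "continuous", "covariate"),
    variable_spec("Sex", "binary", "covariate"),
    variable_spec("Incomplete", "binary", "covariate"),
    variable_spec("OwnHome", "binary", "covariate"),
    variable_spec("DaysSinceInjury", "continuous", "covariate"))
}

cut_latent <- function(z, cum_probs) {
  zs <- (z - mean(z)) / stats::sd(z)
  findInterval(zs, stats::qnorm(cum_probs)) + 1L
}

#' Generate a synthetic survey cohort from a planted truth
#'
#' Samples the 30 binary SHC items from the planted Ising truth, then builds
#' the five outcomes so that each outcome's linear predictor carries
#' `outcome_effect` times the centered true SHC count (with the harmful
#' sign: more conditions mean more unmet care need, lower physical/mental
#' scores, lower satisfaction). A shared latent links the satisfaction and
#' QoL items, a shared latent correlates the physical and mental scores,
#' and depression additionally lowers the mental score. Covariates (age,
#' sex, lesion completeness, living setting, days since injury) are drawn
#' independently with survey-like margins.
#'
#' @param config A [cohort_config()].
#' @return A list of class `synthetic_cohort` with elements `dataset`
#'   (a [survey_dataset()]), `truth` (the generating `truth_network`), and
#'   `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n
  e <- config$outcome_effect
  rel <- e / 0.174   # scales auxiliary planted effects with the main one

  x <- sample_ising_gibbs(config$truth, n, burn_in = 200L, thin = 5L,
                          seed = config$seed)
  # continue the RNG stream started inside the sampler
  #
  # Outcome linear predictors carry the burden of network-connected items
  # only: the planted isolated comorbidities are outcome-unlinked by
  # construction, so they are jointly null in the bivariate screen and
  # dropping them from the index loses no outcome signal.
  linked <- setdiff(colnames(x), config$truth$isolated)
  md <- rowSums(x[, linked, drop = FALSE]) - config$count_center

  g <- stats::rnorm(n)            # shared physical/mental latent
  pcs <- 33.5 - 4.6 * e * md + 4 * g + stats::rnorm(n, 0, config$noise_pcs)
  mcs <- 51.0 - 4.6 * e * md - 6 * rel * x[, "Depre"] + 4 * g +
    stats::rnorm(n, 0, config$noise_mcs)

  ql <- stats::rnorm(n)           # shared satisfaction/QoL latent
  lisat_lat <- -e * md + 1.2 * ql + stats::rnorm(n)
  qol_lat <- -e * md + 1.2 * ql + stats::rnorm(n)
  lisat <- cut_latent(lisat_lat, c(.05, .15, .30, .60, .85))
  qol <- cut_latent(qol_lat, c(.08, .25, .55, .85))

  eta <- stats::qlogis(config$fncnr_prev) + e * md
  fncnr <- stats::rbinom(n, 1L, stats::plogis(eta))

  age <- round(stats::rnorm(n, 48, 13))
  sex <- stats::rbinom(n, 1L, 0.7)
  incomplete <- stats::rbinom(n, 1L, 0.6)
  own_home <- stats::rbinom(n, 1L, 0.7)
  days <- round(stats::rgamma(n, shape = 2, scale = 3400))

  values <- data.frame(id = seq_len(n), as.data.frame(x),
                       FNCNR = fncnr, PCS = pcs, MCS = mcs,
                       LiSAT = lisat, QoL = qol,
                       Age = age, Sex = sex, Incomplete = incomplete,
                       OwnHome = own_home, DaysSinceInjury = days)

  specs <- default_survey_specs()

  structure(list(dataset = survey_dataset(values, specs,
                                          config$cohort_label),
                 truth = config$truth, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> n =", x$config$n, "seed =", x$config$seed,
      "outcome_effect =", x$config$outcome_effect, "\n")
  print(x$dataset)
  invisible(x)
}
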