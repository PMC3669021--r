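#' Specification for a synthetic phenotype dataset
#'
#' Describes a binary strain x resource matrix with planted structure of the
#' kind culture-based phenotyping produces: groups of strains with identical
#' profiles (equivalence classes), groups of resources with identical
#' utilization columns, a block of universal resources every strain uses, a
#' block of unused resources, independent cell-flip noise, and a continuous
#' optical-density variant whose values are bimodal (a no-growth noise mode
#' near zero and a growth signal mode well above it).
#'
#' Defaults emulate a Biolog PM-scale carbon-utilization screen: 33 isolates
#' by 95 substrates with 6 planted strain classes, 13 universal and 4 unused
#' substrates, 2% flip noise, growth signal N(1.5, 0.1) OD versus blank noise
#' N(0.05, 0.02) OD.
#'
#' @param n_strains,n_resources matrix dimensions.
#' @param n_strain_classes,n_resource_classes number of planted classes;
#'   resource classes count only the free (non-universal, non-unused)
#'   columns.
#' @param noise_flip_prob per-cell flip probability in \[0, 1), applied to
#'   free columns only so the universal/unused blocks stay clean.
#' @param n_universal_resources,n_unused_resources forced all-one / all-zero
#'   columns.
#' @param od_signal_mean,od_signal_sd,od_noise_mean,od_noise_sd parameters of
#'   the two OD modes for the continuous variant (dimensionless absorbance).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return a validated list of class `"synth_spec"`.
#' @export
synth_spec <- function(n_strains = 33L, n_resources = 95L,
                       n_strain_classes = 6L, n_resource_classes = 8L,
                       noise_flip_prob = 0.02,
                       n_universal_resources = 13L, n_unused_resources = 4L,
                       od_signal_mean = 1.5, od_signal_sd = 0.1,
                       od_noise_mean = 0.05, od_noise_sd = 0.02,
                       seed = NULL) {
  spec <- list(n_strains = as.integer(n_strains),
               n_resources = as.integer(n_resources),
               n_strain_classes = as.integer(n_strain_classes),
               n_resource_classes = as.integer(n_resource_classes),
               noise_flip_prob = noise_flip_prob,
               n_universal_resources = as.integer(n_universal_resources),
               n_unused_resources = as.integer(n_unused_resources),
               od_signal_mean = od_signal_mean, od_signal_sd = od_signal_sd,
               od_noise_mean = od_noise_mean, od_noise_sd = od_noise_sd,
               seed = if (is.null(seed)) NULL else as.integer(seed))
  with(spec, {
    if (n_strains < 1L || n_resources < 1L)
      stop("need at least one strain and one resource", call. = FALSE)
    if (n_strain_classes < 1L || n_strain_classes > n_strains)
      stop("n_strain_classes must be in [1, n_strains]", call. = FALSE)
    if (n_universal_resources < 0L || n_unused_resources < 0L ||
        n_universal_resources + n_unused_resources > n_resources)
      stop("universal + unused resources exceed n_resources", call. = FALSE)
    free <- n_resources - n_universal_resources - n_unused_resources
    if (n_resource_classes < 0L || n_resource_classes > free)
      stop("n_resource_classes must be in [0, free resources]", call. = FALSE)
    if (free > 0L && n_resource_classes == 0L)
      stop("free resources present but n_resource_classes is 0", call. = FALSE)
    if (noise_flip_prob < 0 || noise_flip_prob >= 1)
      stop("noise_flip_prob must be in [0, 1)", call. = FALSE)
    if (od_signal_sd < 0 || od_noise_sd < 0)
      stop("OD standard deviations must be non-negative", call. = FALSE)
  })
  structure(spec, class = "synth_spec")
}

#' Simulate a binary phenotype matrix with planted class structure
#'
#' Draws distinct canonical profiles for the planted classes, assigns every
#' strain to a class (each class non-empty), forces the universal and unused
#' columns, flips the remaining cells independently with the configured noise
#' probability, and shuffles column positions. With zero noise,
#' [compute_strain_classes()] recovers the planted partition exactly.
#'
#' @param spec a [synth_spec()].
#' @return list of class `"synth_binary"`: `matrix` (a `phenotype_matrix`),
#'   `truth` with `strain_membership` (named integer vector of planted class
#'   indices), `resource_membership` (named character vector: planted free
#'   class id, `"universal"` or `"unused"`), `universal`, `unused` (resource
#'   names), and `spec`.
#' @export
simulate_binary <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  k <- spec$n_strain_classes
  l <- spec$n_resource_classes
  free <- spec$n_resources - spec$n_universal_resources -
    spec$n_unused_resources
  if (l > 0 && k > 2^l)
    stop("infeasible: ", k, " distinct profiles demanded over ", l,
         " free resource classes", call. = FALSE)
  if (l == 0L && k > 1L)
    stop("infeasible: multiple strain classes but no free resources",
         call. = FALSE)

  core <- draw_core(k, l, forbid_all_one = spec$n_universal_resources > 0L,
                    forbid_all_zero = spec$n_unused_resources > 0L)

  strain_membership <- sample(c(seq_len(k),
                                sample.int(k, spec$n_strains - k,
                                           replace = TRUE)))
  # free resources spread over l groups, each non-empty, then all column
  # roles shuffled into their final positions
  free_groups <- if (l > 0L)
    sample(c(seq_len(l), sample.int(l, free - l, replace = TRUE)))
  else integer(0)
  free_roles <- if (l > 0L) paste0("G", free_groups) else character(0)
  roles <- sample(c(free_roles,
                    rep("universal", spec$n_universal_resources),
                    rep("unused", spec$n_unused_resources)))

  vals <- matrix(0L, spec$n_strains, spec$n_resources)
  for (j in seq_len(spec$n_resources)) {
    role <- roles[j]
    vals[, j] <- if (role == "universal") 1L
    else if (role == "unused") 0L
    else core[strain_membership, as.integer(sub("G", "", role))]
  }
  if (spec$noise_flip_prob > 0) {
    flippable <- !(roles %in% c("universal", "unused"))
    flip <- matrix(stats::runif(length(vals)) < spec$noise_flip_prob,
                   nrow(vals))
    flip[, !flippable] <- FALSE
    vals[flip] <- 1L - vals[flip]
  }
  strains <- sprintf("S%03d", seq_len(spec$n_strains))
  resources <- sprintf("C%03d", seq_len(spec$n_resources))
  m <- phenotype_matrix(vals, strains, resources)
  membership <- stats::setNames(roles, resources)
  structure(list(
    matrix = m,
    truth = list(
      strain_membership = stats::setNames(strain_membership, strains),
      resource_membership = membership,
      universal = resources[roles == "universal"],
      unused = resources[roles == "unused"]),
    spec = spec
  ), class = "synth_binary")
}

# Distinct canonical profiles: k x l, rows pairwise distinct, columns
# pairwise distinct, all-one/all-zero columns excluded when universal/unused
# blocks already occupy those roles. Rejection-sampled; the feasibility
# checks above make success overwhelmingly likely for sane shapes.
draw_core <- function(k, l, forbid_all_one, forbid_all_zero) {
  if (l == 0L) return(matrix(integer(0), k, 0L))
  max_cols <- 2^k - forbid_all_one - forbid_all_zero
  if (l > max_cols)
    stop("infeasible: ", l, " distinct resource classes over ", k,
         " strain classes", call. = FALSE)
  for (try in seq_len(10000L)) {
    core <- matrix(stats::rbinom(k * l, 1L, 0.5), k, l)
    if (forbid_all_one && any(colSums(core) == k)) next
    if (forbid_all_zero && any(colSums(core) == 0L)) next
    if (anyDuplicated(apply(core, 1L, paste, collapse = ""))) next
    if (anyDuplicated(apply(core, 2L, paste, collapse = ""))) next
    return(core)
  }
  stop("could not draw distinct canonical profiles; spec too tight",
       call. = FALSE)
}

#' Simulate continuous optical-density measurements over a planted truth
#'
#' First simulates a binary truth with [simulate_binary()], then replaces
#' each cell by a draw from the growth-signal distribution (truth 1) or the
#' no-growth noise distribution (truth 0), truncated at zero. When the two
#' modes are well separated, [binarize()] at the default 10%-of-maximum rule
#' recovers the truth.
#'
#' @param spec a [synth_spec()].
#' @return list of class `"synth_continuous"`: `matrix` (a
#'   `continuous_matrix`), `truth` (the binary `phenotype_matrix` the draws
#'   encode), `binary` (the full `synth_binary` object), `spec`.
#' @export
simulate_continuous <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  sb <- simulate_binary(spec)
  truth <- unclass(sb$matrix)
  draws <- matrix(stats::rnorm(
    length(truth),
    mean = ifelse(truth == 1L, spec$od_signal_mean, spec$od_noise_mean),
    sd = ifelse(truth == 1L, spec$od_signal_sd, spec$od_noise_sd)),
    nrow(truth))
  draws <- pmax(draws, 0)
  structure(list(
    matrix = continuous_matrix(draws, rownames(sb$matrix),
                               colnames(sb$matrix)),
    truth = sb$matrix,
    binary = sb,
    spec = spec
  ), class = "synth_continuous")
}
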