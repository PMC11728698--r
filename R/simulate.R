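#' Simulation configuration
#'
#' Bundles the parameters of the profile-level community simulator. The
#' defaults emulate the scale of a human-gut benchmarking scenario: 343
#' samples over a universe of 1000 species, with per-sample richness
#' around 200 and long-tailed (log-normal) relative abundances, giving
#' Shannon diversities around 5 nats.
#'
#' @param n_samples Number of samples.
#' @param n_features Size of the feature universe.
#' @param richness_mean Target number of nonzero features per sample;
#'   per-sample richness is drawn as rounded
#'   `Normal(richness_mean, richness_mean/10)` clipped to
#'   `[1, n_features]`.
#' @param abundance_mu,abundance_sigma Log-scale location and standard
#'   deviation of the log-normal abundance law (the location cancels
#'   under closure to unit sum; the scale sets the tail).
#' @param dropout_rate_at_min Probability that the rarest feature of a
#'   sample is missed by the simulated profiler; the dropout probability
#'   decreases linearly in log-abundance to 0 at the most abundant
#'   feature.
#' @param fp_injection_rate Poisson mean of spurious (false-positive)
#'   features added per sample.
#' @param confusion_pairs List of `(source, sink, fraction)` triples (or
#'   a 3-column data frame): a `fraction` of the source feature's
#'   abundance is rerouted to the sink feature in every sample where the
#'   source is present.
#' @param noise_sigma Standard deviation of the multiplicative
#'   log-normal measurement noise on surviving entries.
#' @param unmapped_fraction,split_fraction Fractions of native features
#'   that [generate_mapping()] leaves unmapped / splits across two
#'   common-space targets.
#' @param seed Integer seed making every generator deterministic.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_samples = 343L, n_features = 1000L,
                       richness_mean = 200L,
                       abundance_mu = 0, abundance_sigma = 1,
                       dropout_rate_at_min = 0, fp_injection_rate = 0,
                       confusion_pairs = list(), noise_sigma = 0,
                       unmapped_fraction = 0, split_fraction = 0,
                       seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_features = as.integer(n_features),
              richness_mean = as.integer(richness_mean),
              abundance_mu = abundance_mu,
              abundance_sigma = abundance_sigma,
              dropout_rate_at_min = dropout_rate_at_min,
              fp_injection_rate = fp_injection_rate,
              confusion_pairs = normalize_confusion_pairs(confusion_pairs),
              noise_sigma = noise_sigma,
              unmapped_fraction = unmapped_fraction,
              split_fraction = split_fraction,
              seed = as.integer(seed))
  with(cfg, {
    if (n_samples < 1L) stop("n_samples must be positive")
    if (n_features < 2L) stop("n_features must be at least 2")
    if (richness_mean < 1L || richness_mean > n_features)
      stop("richness_mean must lie in [1, n_features]")
    if (abundance_sigma < 0) stop("abundance_sigma must be nonnegative")
    if (dropout_rate_at_min < 0 || dropout_rate_at_min > 1)
      stop("dropout_rate_at_min must lie in [0, 1]")
    if (fp_injection_rate < 0) stop("fp_injection_rate must be nonnegative")
    if (noise_sigma < 0) stop("noise_sigma must be nonnegative")
    if (unmapped_fraction < 0 || split_fraction < 0 ||
        unmapped_fraction + split_fraction > 1)
      stop("unmapped_fraction + split_fraction must lie in [0, 1]")
  })
  structure(cfg, class = "sim_config")
}

normalize_confusion_pairs <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(ncol(x) >= 3L)
    x <- lapply(seq_len(nrow(x)), function(i)
      list(source = as.character(x[i, 1L]), sink = as.character(x[i, 2L]),
           fraction = as.numeric(x[i, 3L])))
  }
  lapply(x, function(p) {
    p <- stats::setNames(as.list(p), c("source", "sink", "fraction"))
    p$fraction <- as.numeric(p$fraction)
    if (p$fraction < 0 || p$fraction > 1)
      stop("confusion fraction must lie in [0, 1]")
    p
  })
}

#' Generate a ground-truth community abundance table
#'
#' Per sample: richness is drawn as rounded
#' `Normal(richness_mean, richness_mean/10)` (clipped to the feature
#' universe), that many features are selected uniformly, abundances are
#' drawn i.i.d. log-normal and closed to sum 1. Deterministic given the
#' config seed.
#'
#' @param config A [sim_config()].
#' @return A normalized [abundance_table()] with all `n_features` rows
#'   (absent features are exact zeros).
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  feats <- sprintf("sp%04d", seq_len(config$n_features))
  samples <- sprintf("sample%03d", seq_len(config$n_samples))
  tab <- matrix(0, config$n_features, config$n_samples,
                dimnames = list(feats, samples))
  for (j in seq_len(config$n_samples)) {
    rich <- round(stats::rnorm(1L, config$richness_mean,
                               config$richness_mean / 10))
    rich <- min(max(rich, 1L), config$n_features)
    present <- sample.int(config$n_features, rich)
    ab <- stats::rlnorm(rich, config$abundance_mu, config$abundance_sigma)
    tab[present, j] <- ab / sum(ab)
  }
  abundance_table(tab, normalized = TRUE)
}

#' Simulate a profiler's estimate from a ground-truth table
#'
#' Applies parameterized error modes to the truth, in a fixed order:
#' (1) confusion — each configured `(source, sink, fraction)` reroutes
#' that fraction of the source's abundance to the sink wherever the
#' source is present; (2) dropout — each present feature is dropped with
#' probability decreasing linearly in log-abundance, from
#' `dropout_rate_at_min` at the sample minimum to 0 at the maximum
#' (rare features are missed preferentially); (3) false-positive
#' injection — `Poisson(fp_injection_rate)` absent features are added at
#' abundances drawn uniformly below the sample's median nonzero truth
#' abundance; (4) multiplicative log-normal noise
#' `exp(Normal(0, noise_sigma))` on surviving entries. Columns are then
#' renormalized. Deterministic given `seed`.
#'
#' @param truth A normalized [abundance_table()] (typically from
#'   [generate_truth()]).
#' @param config A [sim_config()].
#' @param seed Seed for the profiler's error draws; defaults to
#'   `config$seed + 1` so truth and error draws are decoupled.
#' @return A normalized [abundance_table()] over the same feature
#'   universe.
#' @export
simulate_profiler <- function(truth, config, seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"), is.matrix(truth))
  feats <- rownames(truth)
  for (p in config$confusion_pairs) {
    if (!p$source %in% feats)
      stop("confusion source '", p$source, "' absent from feature universe")
    if (!p$sink %in% feats)
      stop("confusion sink '", p$sink, "' absent from feature universe")
  }
  no_error <- length(config$confusion_pairs) == 0L &&
    config$dropout_rate_at_min == 0 && config$fp_injection_rate == 0 &&
    config$noise_sigma == 0
  if (no_error) return(truth)   # zero error model: the estimate IS the truth
  set.seed(seed)
  est <- unclass(truth)

  # (1) confusion: reroute a fraction of source abundance to the sink
  for (p in config$confusion_pairs) {
    src <- est[p$source, ]
    moved <- src * p$fraction
    est[p$source, ] <- src - moved
    est[p$sink, ] <- est[p$sink, ] + moved
  }

  for (j in seq_len(ncol(est))) {
    x <- est[, j]
    nz <- which(x > 0)
    # (2) dropout, preferential for rare features
    if (config$dropout_rate_at_min > 0 && length(nz) > 0L) {
      lx <- log(x[nz])
      span <- max(lx) - min(lx)
      pdrop <- if (span == 0) rep(0, length(nz)) else
        config$dropout_rate_at_min * (max(lx) - lx) / span
      drop <- stats::runif(length(nz)) < pdrop
      x[nz[drop]] <- 0
      nz <- which(x > 0)
    }
    # (3) false-positive injection below the median truth abundance
    if (config$fp_injection_rate > 0) {
      k <- stats::rpois(1L, config$fp_injection_rate)
      absent <- which(unclass(truth)[, j] == 0 & x == 0)
      k <- min(k, length(absent))
      if (k > 0L) {
        tnz <- unclass(truth)[, j]
        tnz <- tnz[tnz > 0]
        hi <- if (length(tnz) > 0L) stats::median(tnz) else 1e-3
        lo <- if (length(tnz) > 0L) min(tnz) / 10 else 1e-6
        picked <- if (length(absent) == 1L) absent else
          sample(absent, k)
        x[picked] <- stats::runif(k, lo, hi)
      }
    }
    # (4) multiplicative measurement noise
    if (config$noise_sigma > 0) {
      nz <- which(x > 0)
      x[nz] <- x[nz] * exp(stats::rnorm(length(nz), 0, config$noise_sigma))
    }
    s <- sum(x)
    if (s > 0) x <- x / s
    est[, j] <- x
  }
  abundance_table(est, normalized = all(colSums(est) > 0))
}

#' Generate a synthetic native-to-common feature mapping
#'
#' Emulates the structure of a cross-catalogue projection: a fraction of
#' native features has no common-space correspondence (unmapped), a
#' fraction maps to two common features with equal 0.5/0.5 weights
#' (split), and the remainder maps one-to-one — with some distinct
#' native features sharing a common target (many-to-one), as happens
#' when a finer catalogue is projected onto a coarser one. Counts use
#' deterministic rounding (`round(fraction * n)`); assignment is
#' seed-deterministic.
#'
#' @param feature_ids Native feature ids.
#' @param config A [sim_config()] (uses `unmapped_fraction`,
#'   `split_fraction`, `seed`).
#' @return A [feature_mapping()].
#' @export
generate_mapping <- function(feature_ids, config) {
  stopifnot(inherits(config, "sim_config"))
  n <- length(feature_ids)
  set.seed(config$seed + 2L)
  n_unmapped <- round(config$unmapped_fraction * n)
  n_split <- round(config$split_fraction * n)
  shuffled <- sample(feature_ids)
  unmapped <- shuffled[seq_len(n_unmapped)]
  split <- shuffled[seq_len(n_split) + n_unmapped]
  one2one <- shuffled[seq.int(n_unmapped + n_split + 1L, length.out =
                                n - n_unmapped - n_split)]
  # one-to-one natives get unique targets (a pure renaming when no
  # feature is split or unmapped); split features reuse targets from that
  # pool, so distinct natives share a common target whenever splits occur
  pool <- sprintf("common%04d", seq_along(one2one))
  native <- character(0); common <- character(0); weight <- numeric(0)
  if (length(one2one) > 0L) {
    native <- c(native, one2one)
    common <- c(common, pool)
    weight <- c(weight, rep(1, length(one2one)))
  }
  if (length(split) > 0L) {
    for (i in seq_along(split)) {
      tgt <- if (length(pool) >= 2L) sample(pool, 2L) else
        sprintf("split%04d", 2L * i - 1:0)
      native <- c(native, rep(split[i], 2L))
      common <- c(common, tgt)
      weight <- c(weight, c(0.5, 0.5))
    }
  }
  if (length(native) == 0L) stop("all features unmapped; nothing to project")
  ord <- order(match(native, feature_ids))
  feature_mapping(native[ord], common[ord], weight[ord])
}

#' Generate a random phylogeny over a feature set
#'
#' Random rooted binary topology (successive random joins, via
#' [ape::rtree()]) with i.i.d. exponential branch lengths of mean 0.1,
#' supplying the branch lengths the weighted UniFrac distance needs.
#' Deterministic given `seed`.
#'
#' @param feature_ids At least two feature ids (the leaf labels).
#' @param seed Integer seed.
#' @return A `phylo` tree.
#' @export
generate_tree <- function(feature_ids, seed = 1L) {
  n <- length(feature_ids)
  if (n < 2L) stop("need at least 2 features to build a tree")
  set.seed(seed)
  tree <- ape::rtree(n, rooted = TRUE, tip.label = feature_ids,
                     br = function(k) stats::rexp(k, rate = 10))
  tree
}

#' Generate a full synthetic evaluation scenario
#'
#' Convenience wrapper producing all inputs the pipeline consumes:
#' ground truth, simulated profiler estimate, feature mapping and
#' phylogeny, all deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return List with elements `truth`, `est`, `mapping`, `tree`,
#'   `config`.
#' @export
generate_scenario <- function(config) {
  truth <- generate_truth(config)
  est <- simulate_profiler(truth, config)
  mapping <- generate_mapping(rownames(truth), config)
  tree <- generate_tree(rownames(truth), seed = config$seed + 3L)
  list(truth = truth, est = est, mapping = mapping, tree = tree,
       config = config)
}
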