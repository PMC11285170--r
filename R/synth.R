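#' Synthetic open-set source/target dataset pairs
#'
#' Generates labeled source and unlabeled target datasets with known ground
#' truth, emulating the open-set annotation setting: each cell type has a
#' disjoint set of marker peaks that are accessible with probability `p_open`
#' in cells of that type and `p_background` elsewhere; the target batch is
#' distribution-shifted on the logit scale (`batch_logit_shift`); a configurable
#' number of cell types appears only in the target ("unknown" types).
#'
#' ATAC matrices are drawn from the per-type Bernoulli product law directly:
#' the annotation model consumes binarized matrices, so the binarized law is
#' what matters. Cell counts per type are deterministic (largest-remainder
#' apportionment of the requested proportions), so fixture shapes are stable.
#'
#' @param n_source,n_target number of source / target cells.
#' @param n_peaks number of features (peaks or genes).
#' @param n_known_types number of cell types present in the labeled source (K).
#' @param n_unknown_types number of extra types present only in the target.
#' @param p_open accessibility probability on a type's marker peaks.
#' @param p_background accessibility probability elsewhere.
#' @param marker_peaks_per_type size of each type's disjoint marker block.
#' @param batch_logit_shift additive shift applied to target accessibility
#'   logits (the simulated batch effect).
#' @param source_proportions,target_proportions optional type proportions;
#'   source over the K known types, target over known + unknown types.
#'   Defaults: uniform source; target gives 20% of cells to the unknown types
#'   (split evenly) and the rest uniformly to known types.
#' @param seed integer RNG seed; generation is deterministic given the config.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_source = 500L, n_target = 500L, n_peaks = 2000L,
                         n_known_types = 4L, n_unknown_types = 1L,
                         p_open = 0.6, p_background = 0.05,
                         marker_peaks_per_type = 150L,
                         batch_logit_shift = 0.5,
                         source_proportions = NULL,
                         target_proportions = NULL,
                         seed = 0L) {
  cfg <- list(n_source = as.integer(n_source), n_target = as.integer(n_target),
              n_peaks = as.integer(n_peaks),
              n_known_types = as.integer(n_known_types),
              n_unknown_types = as.integer(n_unknown_types),
              p_open = p_open, p_background = p_background,
              marker_peaks_per_type = as.integer(marker_peaks_per_type),
              batch_logit_shift = batch_logit_shift,
              source_proportions = source_proportions,
              target_proportions = target_proportions,
              seed = as.integer(seed))
  n_types <- cfg$n_known_types + cfg$n_unknown_types
  if (!(cfg$p_background > 0 && cfg$p_background < cfg$p_open && cfg$p_open < 1)) {
    stop("need 0 < p_background < p_open < 1")
  }
  if (cfg$marker_peaks_per_type * n_types > cfg$n_peaks) {
    stop("marker blocks (", cfg$marker_peaks_per_type * n_types,
         " peaks) exceed n_peaks (", cfg$n_peaks, ")")
  }
  if (cfg$n_known_types < 1L || cfg$n_source < 1L || cfg$n_target < 1L) {
    stop("counts must be positive")
  }
  class(cfg) <- "synth_config"
  cfg
}

synth_type_names <- function(cfg) {
  known <- paste0("C", seq_len(cfg$n_known_types))
  unknown <- if (cfg$n_unknown_types > 0L) {
    paste0("U", seq_len(cfg$n_unknown_types))
  } else character()
  list(known = known, unknown = unknown, all = c(known, unknown))
}

# deterministic apportionment of n cells to proportions (largest remainder)
apportion <- function(n, props) {
  props <- props / sum(props)
  raw <- n * props
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  as.integer(counts)
}

default_proportions <- function(cfg) {
  src <- cfg$source_proportions %||% rep(1 / cfg$n_known_types, cfg$n_known_types)
  tgt <- cfg$target_proportions
  if (is.null(tgt)) {
    if (cfg$n_unknown_types > 0L) {
      tgt <- c(rep(0.8 / cfg$n_known_types, cfg$n_known_types),
               rep(0.2 / cfg$n_unknown_types, cfg$n_unknown_types))
    } else {
      tgt <- rep(1 / cfg$n_known_types, cfg$n_known_types)
    }
  }
  if (length(src) != cfg$n_known_types ||
      length(tgt) != cfg$n_known_types + cfg$n_unknown_types ||
      any(src < 0) || any(tgt < 0) || sum(src) <= 0 || sum(tgt) <= 0) {
    stop("invalid type proportions")
  }
  list(source = src / sum(src), target = tgt / sum(tgt))
}

# marker peak indices per type; disjoint consecutive blocks
marker_blocks <- function(cfg) {
  n_types <- cfg$n_known_types + cfg$n_unknown_types
  lapply(seq_len(n_types), function(t) {
    ((t - 1L) * cfg$marker_peaks_per_type + 1L):(t * cfg$marker_peaks_per_type)
  })
}

# accessibility probability vector (length n_peaks) for one type
type_open_probs <- function(cfg, type_index, markers) {
  q <- rep(cfg$p_background, cfg$n_peaks)
  q[markers[[type_index]]] <- cfg$p_open
  q
}

draw_bernoulli_block <- function(n_cells, q) {
  m <- length(q)
  u <- matrix(runif(n_cells * m), n_cells, m)
  q_mat <- matrix(q, n_cells, m, byrow = TRUE)
  (u < q_mat) * 1
}

#' Generate a synthetic scATAC source/target pair
#'
#' @param cfg a [synth_config()].
#' @return A list of class `synth_pair` with elements `source` (labeled
#'   [raw_dataset()] over the known types), `target` (unlabeled
#'   [raw_dataset()]), `truth` (true per-target-cell labels, including
#'   target-only types), and `known_types`.
#' @export
generate_atac <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, {
    nm <- synth_type_names(cfg)
    props <- default_proportions(cfg)
    markers <- marker_blocks(cfg)
    peaks <- sprintf("chr1:%d-%d", (seq_len(cfg$n_peaks) - 1L) * 1000L,
                     (seq_len(cfg$n_peaks) - 1L) * 1000L + 500L)

    src_counts <- apportion(cfg$n_source, props$source)
    tgt_counts <- apportion(cfg$n_target, props$target)
    if (cfg$n_unknown_types > 0L &&
        any(tgt_counts[cfg$n_known_types + seq_len(cfg$n_unknown_types)] < 1L)) {
      stop("invalid proportions: an unknown type received no target cells")
    }

    build <- function(counts, type_indices, shift) {
      rows <- vector("list", length(type_indices))
      labels <- character()
      for (k in seq_along(type_indices)) {
        t <- type_indices[k]
        q <- type_open_probs(cfg, t, markers)
        if (shift != 0) q <- plogis(qlogis(q) + shift)
        rows[[k]] <- draw_bernoulli_block(counts[k], q)
        labels <- c(labels, rep(nm$all[t], counts[k]))
      }
      list(x = do.call(rbind, rows), labels = labels)
    }

    src <- build(src_counts, seq_len(cfg$n_known_types), 0)
    tgt <- build(tgt_counts, seq_len(cfg$n_known_types + cfg$n_unknown_types),
                 cfg$batch_logit_shift)

    # shuffle cells so type blocks are not contiguous
    src_ord <- sample.int(nrow(src$x))
    tgt_ord <- sample.int(nrow(tgt$x))

    source <- raw_dataset(src$x[src_ord, , drop = FALSE], peaks,
                          sprintf("src_%04d", seq_len(cfg$n_source)),
                          labels = src$labels[src_ord], modality = "atac")
    target <- raw_dataset(tgt$x[tgt_ord, , drop = FALSE], peaks,
                          sprintf("tgt_%04d", seq_len(cfg$n_target)),
                          labels = NULL, modality = "atac")
    structure(list(source = source, target = target,
                   truth = tgt$labels[tgt_ord], known_types = nm$known,
                   config = cfg),
              class = "synth_pair")
  })
}

#' Generate a synthetic scRNA source/target pair
#'
#' Counts are negative-binomial with type-specific mean programs: every gene
#' gets a log-normal baseline mean, marker genes are up-shifted by
#' `marker_fold` in their type, per-cell library sizes are log-normal around
#' `mean_depth`, and the target batch multiplies gene means by a fixed
#' per-gene log-normal factor with scale `batch_logit_shift`.
#'
#' @param cfg a [synth_config()]; `p_open`/`p_background` are ignored.
#' @param mean_depth expected per-cell total count.
#' @param marker_fold mean fold-change of a marker gene in its own type.
#' @param dispersion negative-binomial size parameter.
#' @return A `synth_pair`, as [generate_atac()].
#' @export
generate_rna <- function(cfg = synth_config(), mean_depth = 5000,
                         marker_fold = 4, dispersion = 2) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, {
    nm <- synth_type_names(cfg)
    props <- default_proportions(cfg)
    markers <- marker_blocks(cfg)
    genes <- sprintf("gene%04d", seq_len(cfg$n_peaks))
    n_types <- cfg$n_known_types + cfg$n_unknown_types

    base_mean <- exp(rnorm(cfg$n_peaks, 0, 0.5))
    type_means <- lapply(seq_len(n_types), function(t) {
      mu <- base_mean
      mu[markers[[t]]] <- mu[markers[[t]]] * marker_fold
      mu / sum(mu)
    })
    batch_factor <- exp(cfg$batch_logit_shift * rnorm(cfg$n_peaks))

    src_counts <- apportion(cfg$n_source, props$source)
    tgt_counts <- apportion(cfg$n_target, props$target)

    build <- function(counts, type_indices, batch) {
      rows <- vector("list", length(type_indices))
      labels <- character()
      for (k in seq_along(type_indices)) {
        t <- type_indices[k]
        n_c <- counts[k]
        if (n_c == 0L) { rows[[k]] <- NULL; next }
        lib <- exp(rnorm(n_c, log(mean_depth), 0.3))
        mu_g <- type_means[[t]]
        if (batch) mu_g <- mu_g * batch_factor / sum(mu_g * batch_factor)
        mu <- outer(lib, mu_g)
        rows[[k]] <- matrix(rnbinom(n_c * cfg$n_peaks, mu = mu,
                                    size = dispersion),
                            n_c, cfg$n_peaks)
        labels <- c(labels, rep(nm$all[t], n_c))
      }
      list(x = do.call(rbind, rows), labels = labels)
    }

    src <- build(src_counts, seq_len(cfg$n_known_types), FALSE)
    tgt <- build(tgt_counts, seq_len(n_types), TRUE)
    src_ord <- sample.int(nrow(src$x))
    tgt_ord <- sample.int(nrow(tgt$x))

    structure(list(
      source = raw_dataset(src$x[src_ord, , drop = FALSE], genes,
                           sprintf("src_%04d", seq_len(cfg$n_source)),
                           labels = src$labels[src_ord], modality = "rna"),
      target = raw_dataset(tgt$x[tgt_ord, , drop = FALSE], genes,
                           sprintf("tgt_%04d", seq_len(cfg$n_target)),
                           labels = NULL, modality = "rna"),
      truth = tgt$labels[tgt_ord], known_types = nm$known, config = cfg),
      class = "synth_pair")
  })
}

#' The canonical synthetic open-set benchmark
#'
#' 4 known cell types plus 1 target-only type, 500 source and 500 target
#' cells (the unknown type is 20% of the target), 2,000 peaks, seed 0.
#'
#' @param seed RNG seed (default 0, the fixture seed).
#' @return A `synth_pair`.
#' @export
default_benchmark <- function(seed = 0L) {
  generate_atac(synth_config(seed = seed))
}
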