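# Dataset construction: score ICA components against the two magnetic
# references, label them by thresholds (delta / lambda), and assemble the
# balanced, inversion-augmented training corpus.
#
# Class coding used throughout: 0 = cardiac artifact, 1 = blink artifact,
# 2 = non-artifact.

CLASS_CARDIAC <- 0L
CLASS_BLINK <- 1L
CLASS_NONE <- 2L

#' Score ICA components against the magnetic reference channels
#'
#' Computes one (rdc_mog, rdc_mcg) pair per component. For efficiency the
#' random-feature draws of each reference and of each component are shared
#' across the pairings inside one call, so the per-pair seed schedule
#' differs from element-wise [rdc()] calls; every pair is still a valid
#' seeded RDC estimate (median over `params$n_repeats` repeats).
#'
#' @param decomposition an `ica_decomposition` from [ica_decompose()].
#' @param mog,mcg ocular / cardiac magnetic reference series covering the
#'   same epoch window as the sources.
#' @param params an [rdc_params()].
#' @param epoch_id index recorded in the output table.
#' @return data.frame with columns `epoch_id`, `component_id`, `rdc_mog`,
#'   `rdc_mcg`.
#' @export
score_components <- function(decomposition, mog, mcg,
                             params = rdc_params(), epoch_id = 1L) {
  if (!inherits(decomposition, "ica_decomposition")) {
    stop("`decomposition` must come from ica_decompose()", call. = FALSE)
  }
  S <- decomposition$sources
  n <- ncol(S)
  if (length(mog) != n || length(mcg) != n) {
    stop("reference series must match the source length", call. = FALSE)
  }
  R <- params$n_repeats
  # Pre-center each signal's feature matrices and factorize their ridged
  # covariances once; every pairing then costs a single cross-covariance.
  prep <- function(x, seed_base) {
    u <- copula_transform(x)
    lapply(seq_len(R), function(r) {
      phi <- rdc_random_features(u, params$k, params$s,
                                 derive_seed(params$seed, seed_base + r))
      pc <- phi - rep(colMeans(phi), each = nrow(phi))
      Sxx <- crossprod(pc) / (nrow(pc) - 1) + diag(params$ridge, ncol(pc))
      list(pc = pc, Kinv = chol2inv(chol(Sxx)))
    })
  }
  pair_score <- function(a, b) {
    vals <- vapply(seq_len(R), function(r) {
      Sxy <- crossprod(a[[r]]$pc, b[[r]]$pc) / (nrow(a[[r]]$pc) - 1)
      M <- (a[[r]]$Kinv %*% Sxy) %*% (b[[r]]$Kinv %*% t(Sxy))
      ev <- eigen(M, only.values = TRUE)$values
      sqrt(min(1, max(0, Re(ev[which.max(Re(ev))]))))
    }, numeric(1))
    min(1, max(0, stats::median(vals)))
  }
  refs <- list(mog = prep(mog, 500000), mcg = prep(mcg, 1000000))
  sc <- vapply(seq_len(decomposition$n_components), function(i) {
    comp <- prep(S[i, ], i * 1000)
    c(mog = pair_score(comp, refs$mog), mcg = pair_score(comp, refs$mcg))
  }, numeric(2))
  data.frame(epoch_id = epoch_id,
             component_id = seq_len(decomposition$n_components),
             rdc_mog = sc["mog", ], rdc_mcg = sc["mcg", ])
}

#' Label components from their reference correlation scores
#'
#' Per epoch, the blink label goes to the single component with the highest
#' `rdc_mog` among those exceeding `delta` (at most one per epoch per
#' reference); the cardiac label analogously via `rdc_mcg`. Components with
#' both scores below `lambda` are non-artifacts. Components in the gap
#' `[lambda, delta]`, or above `delta` but not maximal, stay unlabeled
#' (`NA`) and are excluded from the corpus. If one component is the top
#' candidate for both references it takes the class of the larger score
#' (ties toward cardiac, the more stereotyped morphology) and the other
#' reference falls back to its next-highest candidate.
#'
#' @param table score table from [score_components()] (rows from several
#'   epochs may be concatenated).
#' @param delta artifact threshold (`delta > lambda`).
#' @param lambda non-artifact threshold (`>= 0`).
#' @return `table` with an integer `label` column: 0 cardiac, 1 blink,
#'   2 none, `NA` unlabeled.
#' @export
label_components <- function(table, delta = 0.3, lambda = 0.2) {
  if (!(delta > lambda && lambda >= 0)) {
    stop("thresholds must satisfy delta > lambda >= 0", call. = FALSE)
  }
  table$label <- NA_integer_
  for (ep in unique(table$epoch_id)) {
    idx <- which(table$epoch_id == ep)
    mog <- table$rdc_mog[idx]
    mcg <- table$rdc_mcg[idx]
    cand_b <- idx[mog > delta][order(mog[mog > delta], decreasing = TRUE)]
    cand_c <- idx[mcg > delta][order(mcg[mcg > delta], decreasing = TRUE)]
    top_b <- if (length(cand_b)) cand_b[1] else NA_integer_
    top_c <- if (length(cand_c)) cand_c[1] else NA_integer_
    if (!is.na(top_b) && !is.na(top_c) && top_b == top_c) {
      if (table$rdc_mog[top_b] > table$rdc_mcg[top_c]) {
        top_c <- if (length(cand_c) > 1) cand_c[2] else NA_integer_
      } else {
        top_b <- if (length(cand_b) > 1) cand_b[2] else NA_integer_
      }
    }
    if (!is.na(top_b)) table$label[top_b] <- CLASS_BLINK
    if (!is.na(top_c)) table$label[top_c] <- CLASS_CARDIAC
    none <- idx[mog < lambda & mcg < lambda]
    none <- setdiff(none, c(top_b, top_c))
    table$label[none] <- CLASS_NONE
  }
  table
}

new_artifact_dataset <- function(waveforms, labels, provenance) {
  counts <- c(cardiac = sum(labels == CLASS_CARDIAC),
              blink = sum(labels == CLASS_BLINK),
              none = sum(labels == CLASS_NONE))
  structure(list(waveforms = waveforms, labels = as.integer(labels),
                 provenance = provenance, class_counts = counts),
            class = "artifact_dataset")
}

#' @export
print.artifact_dataset <- function(x, ...) {
  cat(sprintf(
    "<artifact_dataset> %d samples x %d points (blink %d, cardiac %d, none %d)\n",
    nrow(x$waveforms), ncol(x$waveforms), x$class_counts[["blink"]],
    x$class_counts[["cardiac"]], x$class_counts[["none"]]))
  invisible(x)
}

standardize_rows <- function(w) {
  mu <- rowMeans(w)
  sds <- apply(w, 1, stats::sd)
  sds[sds == 0] <- 1
  (w - mu) / sds
}

#' Assemble a balanced artifact dataset from labeled component pools
#'
#' Blink and cardiac pools are subsampled (seeded, without replacement) to a
#' common size and the non-artifact pool to `none_factor` times that size,
#' giving the blink : cardiac : none = 1 : 1 : `none_factor` class ratio.
#' Waveforms are standardized to zero mean, unit variance.
#'
#' @param waveforms numeric matrix, one component waveform per row.
#' @param labels integer labels per row (0 cardiac, 1 blink, 2 none;
#'   rows with `NA` labels are dropped).
#' @param provenance optional data.frame (one row per waveform) retained in
#'   the output, e.g. subject/epoch/component indices.
#' @param none_factor non-artifact count per artifact-class count.
#' @param seed integer seed for the subsampling.
#' @return an `artifact_dataset`.
#' @export
assemble_dataset <- function(waveforms, labels, provenance = NULL,
                             none_factor = 4, seed = 1) {
  keep <- !is.na(labels)
  waveforms <- waveforms[keep, , drop = FALSE]
  labels <- labels[keep]
  if (is.null(provenance)) {
    provenance <- data.frame(source_row = which(keep))
  } else {
    provenance <- provenance[keep, , drop = FALSE]
  }
  pools <- list(blink = which(labels == CLASS_BLINK),
                cardiac = which(labels == CLASS_CARDIAC),
                none = which(labels == CLASS_NONE))
  if (any(lengths(pools)[c("blink", "cardiac")] == 0)) {
    stop("both artifact pools must be non-empty", call. = FALSE)
  }
  n_art <- min(length(pools$blink), length(pools$cardiac))
  n_none <- none_factor * n_art
  if (length(pools$none) < n_none) {
    stop(sprintf(
      "insufficient non-artifact samples: need %d, have %d (deficit %d)",
      n_none, length(pools$none), n_none - length(pools$none)),
      call. = FALSE)
  }
  sel <- with_seed(seed, {
    c(sample(pools$cardiac, n_art),
      sample(pools$blink, n_art),
      sample(pools$none, n_none))
  })
  sel <- sort(sel)
  prov <- provenance[sel, , drop = FALSE]
  prov$inverted <- FALSE
  prov$group <- seq_along(sel)
  rownames(prov) <- NULL
  new_artifact_dataset(standardize_rows(waveforms[sel, , drop = FALSE]),
                       labels[sel], prov)
}

#' Augment a dataset with sign-inverted copies
#'
#' ICA component polarity is arbitrary, so every waveform is mirrored by its
#' negation with the same label, doubling the dataset while preserving the
#' class ratio. The `group` provenance column links each inverted copy to
#' its original so the pair can be co-partitioned when splitting.
#'
#' @param dataset an `artifact_dataset`.
#' @return an `artifact_dataset` of twice the size.
#' @export
augment_invert <- function(dataset) {
  if (!inherits(dataset, "artifact_dataset")) {
    stop("`dataset` must be an artifact_dataset", call. = FALSE)
  }
  prov2 <- dataset$provenance
  prov2$inverted <- !prov2$inverted
  new_artifact_dataset(rbind(dataset$waveforms, -dataset$waveforms),
                       c(dataset$labels, dataset$labels),
                       rbind(dataset$provenance, prov2))
}

#' Stratified train/test split with twin co-partitioning
#'
#' Splits by class at `train_frac` (default 4:1). A waveform and its
#' sign-inverted twin (same provenance `group`) always land in the same
#' partition, so no waveform appears in both partitions up to sign.
#'
#' @param dataset an `artifact_dataset`.
#' @param train_frac fraction of each class assigned to training.
#' @param seed integer seed.
#' @return list with `artifact_dataset` elements `train` and `test`.
#' @export
split_dataset <- function(dataset, train_frac = 0.8, seed = 1) {
  if (!inherits(dataset, "artifact_dataset")) {
    stop("`dataset` must be an artifact_dataset", call. = FALSE)
  }
  if (nrow(dataset$waveforms) < 5) {
    stop("dataset too small to split", call. = FALSE)
  }
  grp <- dataset$provenance$group
  train_rows <- with_seed(seed, {
    rows <- integer(0)
    for (cls in c(CLASS_CARDIAC, CLASS_BLINK, CLASS_NONE)) {
      cls_groups <- unique(grp[dataset$labels == cls])
      if (!length(cls_groups)) next
      n_train <- round(train_frac * length(cls_groups))
      g_train <- if (length(cls_groups) == 1) cls_groups else
        sample(cls_groups, n_train)
      rows <- c(rows, which(dataset$labels == cls & grp %in% g_train))
    }
    sort(rows)
  })
  take <- function(rows) {
    new_artifact_dataset(dataset$waveforms[rows, , drop = FALSE],
                         dataset$labels[rows],
                         dataset$provenance[rows, , drop = FALSE])
  }
  list(train = take(train_rows),
       test = take(setdiff(seq_along(dataset$labels), train_rows)))
}

#' Harvest labeled ICA components from one recording
#'
#' Runs the full labeling pipeline on a session: band-pass filter, 10-s
#' epoching, per-epoch FastICA, RDC scoring against the MOG/MCG references,
#' and threshold labeling. The returned waveforms can be pooled across
#' sessions and passed to [assemble_dataset()].
#'
#' @param rec a [recording()].
#' @param subject_id identifier stored in the provenance.
#' @param low,high band-pass edges in Hz.
#' @param epoch_seconds epoch length in seconds.
#' @param n_components ICA components per epoch (default: all MEG channels).
#' @param ica_seed seed for the per-epoch ICA fits.
#' @param params an [rdc_params()].
#' @param delta,lambda labeling thresholds.
#' @param waveform_length if not `NULL`, component waveforms are resampled
#'   to this many points (see [resample_waveform()]) before being returned.
#' @return list with `waveforms` (matrix), `labels` (integer, `NA` for
#'   unlabeled), `provenance` (subject/epoch/component), `scores` (the
#'   labeled score table) and `decompositions`.
#' @export
harvest_components <- function(rec, subject_id = 1L, low = 1.5, high = 40,
                               epoch_seconds = 10, n_components = NULL,
                               ica_seed = 1, params = rdc_params(),
                               delta = 0.3, lambda = 0.2,
                               waveform_length = NULL) {
  filt <- bandpass_filter(rec, low, high)
  es <- segment_epochs(filt, epoch_seconds)
  meg_idx <- which(es$channel_roles == "MEG")
  mog_idx <- which(es$channel_roles == "MOG_REF")
  mcg_idx <- which(es$channel_roles == "MCG_REF")
  if (is.null(n_components)) n_components <- length(meg_idx)
  tables <- list()
  decs <- list()
  waves <- list()
  for (k in seq_along(es$epochs)) {
    ep <- es$epochs[[k]]
    dec <- tryCatch(
      ica_decompose(ep[meg_idx, , drop = FALSE], n_components,
                    seed = derive_seed(ica_seed, k)),
      error = function(e) {
        warning(sprintf("skipping epoch %d: %s", k, conditionMessage(e)),
                call. = FALSE)
        NULL
      })
    if (is.null(dec)) next
    tab <- score_components(dec, ep[mog_idx, ], ep[mcg_idx, ],
                            params = params, epoch_id = k)
    tables[[length(tables) + 1L]] <- tab
    decs[[length(decs) + 1L]] <- dec
    w <- dec$sources
    if (!is.null(waveform_length)) {
      w <- t(apply(w, 1, resample_waveform, target_length = waveform_length))
    }
    waves[[k]] <- w
  }
  scores <- label_components(do.call(rbind, tables), delta, lambda)
  list(waveforms = do.call(rbind, waves),
       labels = scores$label,
       provenance = data.frame(subject = subject_id,
                               epoch = scores$epoch_id,
                               component = scores$component_id),
       scores = scores,
       decompositions = decs)
}

#' Resample a waveform to a target length by regular decimation
#'
#' Picks `target_length` regularly spaced samples. Intended for component
#' waveforms that were band-limited well below the decimated Nyquist rate
#' (e.g. 1.5-40 Hz signals decimated from 10,000 to 2,000 points at an
#' effective 200 Hz), where plain decimation causes no aliasing.
#'
#' @param x numeric vector.
#' @param target_length output length (<= `length(x)`).
#' @return numeric vector of `target_length` samples.
#' @export
resample_waveform <- function(x, target_length) {
  n <- length(x)
  if (target_length > n) {
    stop("target_length must not exceed the waveform length", call. = FALSE)
  }
  if (target_length == n) return(x)
  x[round(seq(1, n, length.out = target_length))]
}
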