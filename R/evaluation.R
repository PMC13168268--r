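#' Load a dataset manifest
#'
#' A dataset directory holds one sub-directory per class, one per
#' session, one event file per transit, and a `manifest.csv` with
#' columns `class, session, sample, file` (paths relative to the
#' directory). Datasets written by [generate_dataset()] also carry a
#' `config.yml`, from which the sensor dimensions are recovered.
#'
#' @param dir dataset directory.
#' @return the manifest data.frame with attributes `dir` and (when the
#'   config is present) `sensor_dims`.
#' @export
load_manifest <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stop("no manifest.csv under '", dir, "'")
  manifest <- as.data.frame(data.table::fread(mf))
  need <- c("class", "session", "sample", "file")
  if (!all(need %in% names(manifest))) {
    stop("manifest must have columns ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(manifest[c("class", "session", "sample")])) {
    stop("duplicate (class, session, sample) triples in manifest")
  }
  attr(manifest, "dir") <- dir
  cfg_path <- file.path(dir, "config.yml")
  if (file.exists(cfg_path)) {
    cfg <- read_simulation_config(cfg_path)
    attr(manifest, "sensor_dims") <- cfg$optics$sensor
  }
  manifest
}

#' Session-aware train/test splits
#'
#' `split_single_session()` mirrors the optimistic protocol in which
#' training and test data of every class come from the same measurement
#' instance: within the named session, each class's samples are shuffled
#' (seeded) and divided `train_fraction` / rest. Any acquisition drift
#' specific to that session is then present identically in training and
#' test data, so class-correlated drift inflates the apparent accuracy —
#' measurement bias.
#'
#' `split_intertwined()` assigns whole sessions to train or test, so the
#' test sessions' drift is never seen in training; session-id sets must
#' be disjoint, which is asserted, making session leakage impossible.
#'
#' @param manifest a dataset manifest (see [load_manifest()]).
#' @param session session id used by the single-session split.
#' @param train_fraction fraction of the session's samples per class
#'   used for training (strictly between 0 and 1; default 10/11,
#'   mirroring a 6,000/600 train/test sizing).
#' @param seed shuffle seed.
#' @return a list with `train` and `test` manifest subsets (disjoint).
#' @export
split_single_session <- function(manifest, session,
                                 train_fraction = 10 / 11, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  classes <- sort(unique(manifest$class))
  tr <- list(); te <- list()
  for (lab in classes) {
    rows <- which(manifest$class == lab & manifest$session == session)
    if (!length(rows)) {
      stop("class ", lab, " has no samples in session ", session)
    }
    perm <- with_seed(derive_seed(seed, "split", lab),
                      sample(rows))
    n_tr <- max(1L, min(length(rows) - 1L,
                        floor(train_fraction * length(rows))))
    tr[[lab]] <- perm[seq_len(n_tr)]
    te[[lab]] <- perm[-seq_len(n_tr)]
  }
  list(train = manifest[sort(unlist(tr)), , drop = FALSE],
       test = manifest[sort(unlist(te)), , drop = FALSE])
}

#' @param train_sessions,test_sessions disjoint session-id sets; every
#'   class must appear in both sets.
#' @rdname split_single_session
#' @export
split_intertwined <- function(manifest, train_sessions, test_sessions) {
  if (length(intersect(train_sessions, test_sessions))) {
    stop("train and test session sets must be disjoint")
  }
  if (!length(train_sessions) || !length(test_sessions)) {
    stop("train and test session sets must be non-empty")
  }
  for (lab in sort(unique(manifest$class))) {
    ses <- manifest$session[manifest$class == lab]
    if (!all(train_sessions %in% ses) || !all(test_sessions %in% ses)) {
      stop("class ", lab, " is missing one of the requested sessions")
    }
  }
  tr <- manifest[manifest$session %in% train_sessions, , drop = FALSE]
  te <- manifest[manifest$session %in% test_sessions, , drop = FALSE]
  stopifnot(length(intersect(tr$file, te$file)) == 0)
  list(train = tr, test = te)
}

#' Evaluate a classifier on a labelled feature set
#'
#' Classifies every row of `features` with [hdc_classify()] and tallies
#' the confusion matrix: `counts[i, j]` is the number of samples of true
#' class `i` predicted as class `j`. The total count always equals the
#' test-set size.
#'
#' @param model an [hdc_train()] model.
#' @param features `n x L` 0/1 matrix of test features.
#' @param labels true class labels, length `n`; must be a subset of the
#'   model's classes.
#' @return an integer confusion matrix (true classes in rows, predicted
#'   in columns) of class `confusion_matrix`.
#' @export
evaluate_model <- function(model, features, labels) {
  labels <- as.character(labels)
  unknown <- setdiff(unique(labels), model$labels)
  if (length(unknown)) {
    stop("test classes not in model: ", paste(unknown, collapse = ", "))
  }
  pred <- hdc_classify(model, features)$labels
  cm <- table(factor(labels, levels = model$labels),
              factor(pred, levels = model$labels))
  cm <- unclass(cm)
  names(dimnames(cm)) <- c("true", "predicted")
  structure(cm, class = c("confusion_matrix", class(cm)))
}

#' Classification accuracy of a confusion matrix
#'
#' Micro-averaged accuracy: trace over total. On class-balanced test
#' sets this equals the mean per-class accuracy.
#'
#' @param cm a square confusion matrix with true classes in rows.
#' @return fraction in `[0, 1]`.
#' @export
accuracy <- function(cm) {
  tot <- sum(cm)
  if (tot == 0) stop("empty confusion matrix")
  sum(diag(as.matrix(cm))) / tot
}

# Train on the train rows and score on the test rows of a prebuilt
# feature set. `fs` is the list returned by build_features(); train/test
# are logical or integer row indices into it.
fit_and_score <- function(fs, train, test, D = NULL, encoder_seed = 1L,
                          tie_seed = 1L) {
  enc <- if (is.null(D)) {
    hdc_encoder(ncol(fs$features))
  } else {
    hdc_encoder(ncol(fs$features), D = D, mode = "subsample",
                seed = encoder_seed)
  }
  model <- hdc_train(fs$features[train, , drop = FALSE], fs$labels[train],
                     encoder = enc, tie_seed = tie_seed)
  evaluate_model(model, fs$features[test, , drop = FALSE],
                 fs$labels[test])
}

# Row indices of a manifest subset within the full manifest.
manifest_rows <- function(manifest, subset) {
  key <- function(m) paste(m$class, m$session, m$sample, sep = "\r")
  match(key(subset), key(manifest))
}

#' Leave-one-session-out accuracy (intertwined protocol)
#'
#' The default intertwined evaluation: each session is held out in turn
#' as the test set while the others train, and the accuracies are
#' averaged. Because train and test sessions are disjoint, per-session
#' drift cannot leak class information.
#'
#' @param fs feature set from [build_features()].
#' @param D optional hypervector dimension; when given, features are
#'   subsampled to D (see [hdc_encoder()]), otherwise used at full
#'   length.
#' @param encoder_seed,tie_seed seeds for the encoder permutation and
#'   majority tie-breaks.
#' @return a list with the mean `accuracy` and the `per_session`
#'   accuracy vector.
#' @export
loso_accuracy <- function(fs, D = NULL, encoder_seed = 1L, tie_seed = 1L) {
  sessions <- sort(unique(fs$sessions))
  if (length(sessions) < 2) stop("leave-one-session-out needs >= 2 sessions")
  acc <- vapply(sessions, function(s) {
    accuracy(fit_and_score(fs, fs$sessions != s, fs$sessions == s,
                           D = D, encoder_seed = encoder_seed,
                           tie_seed = tie_seed))
  }, numeric(1))
  list(accuracy = mean(acc),
       per_session = stats::setNames(acc, sessions))
}

#' Polarity ablation: split versus merged polarity maps
#'
#' Runs the identical train/evaluate pipeline twice on the same dataset
#' and split — once with the positive/negative maps concatenated
#' (polarity kept, twice the feature length) and once with them merged
#' by OR (polarity discarded) — and reports both accuracies. Keeping
#' polarity can only add discriminative information, and on recordings
#' where classes differ in their polarity structure it is strictly
#' better.
#'
#' @param manifest dataset manifest (see [load_manifest()]).
#' @param sensor_dims integer `c(width, height)`.
#' @param split a list with `train` and `test` manifest subsets, e.g.
#'   from [split_intertwined()].
#' @param block OR-pooling block applied to each polarity map.
#' @param dir dataset directory (defaults to the manifest's).
#' @param tie_seed majority tie-break seed.
#' @return named numeric `c(split = ..., merged = ...)` accuracies.
#' @export
polarity_ablation <- function(manifest, sensor_dims, split,
                              block = c(1, 1),
                              dir = attr(manifest, "dir"),
                              tie_seed = 1L) {
  out <- c(split = NA_real_, merged = NA_real_)
  for (mode in c("split", "merged")) {
    fs <- build_features(manifest, sensor_dims, dir = dir, block = block,
                         polarity_mode = mode)
    tr <- manifest_rows(manifest, split$train)
    te <- manifest_rows(manifest, split$test)
    out[mode] <- accuracy(fit_and_score(fs, tr, te, tie_seed = tie_seed))
  }
  out
}

#' Accuracy across feature dimensions (down-sampling sweep)
#'
#' Re-runs the identical pipeline at several OR-pooling block sizes,
#' reporting the pooled map size and accuracy per block. Down-sampling
#' trades feature dimension against computation; presence-preserving
#' pooling keeps coarse patterns informative, so accuracy typically
#' degrades only gently toward small maps.
#'
#' @inheritParams polarity_ablation
#' @param blocks list of integer `c(bh, bw)` block sizes.
#' @param polarity_mode `"split"` or `"merged"`.
#' @return a data.frame with columns `bh, bw, height, width, dim,
#'   accuracy`, one row per block.
#' @export
sweep_feature_dims <- function(manifest, sensor_dims, split, blocks,
                               polarity_mode = "split",
                               dir = attr(manifest, "dir"),
                               tie_seed = 1L) {
  rows <- lapply(blocks, function(b) {
    stopifnot(length(b) == 2, all(b >= 1),
              b[1] <= sensor_dims[2], b[2] <= sensor_dims[1])
    fs <- build_features(manifest, sensor_dims, dir = dir, block = b,
                         polarity_mode = polarity_mode)
    tr <- manifest_rows(manifest, split$train)
    te <- manifest_rows(manifest, split$test)
    acc <- accuracy(fit_and_score(fs, tr, te, tie_seed = tie_seed))
    data.frame(bh = b[1], bw = b[2], height = fs$map_dim[1],
               width = fs$map_dim[2], dim = ncol(fs$features),
               accuracy = acc)
  })
  do.call(rbind, rows)
}

#' Measurement-bias experiment: single-session versus intertwined
#'
#' Generates a fresh dataset per repetition (seeds derived from `seed`)
#' with class-correlated session drift, then scores the same recordings
#' under both protocols: single-session (train and test drawn from one
#' session) and intertwined (leave-one-session-out). When drift is
#' class-correlated, the single-session figure absorbs the drift as if
#' it were class signal and overestimates generalisation, so the gap
#' `single - intertwined` is non-negative in expectation.
#'
#' @param cfg a [simulation_config()] template; its `master_seed` is
#'   replaced per repetition.
#' @param n_reps number of seeded repetitions.
#' @param block OR-pooling block for feature building.
#' @param train_fraction single-session train fraction.
#' @param seed master seed for the repetition seeds.
#' @param dir scratch directory for the generated datasets (a fresh
#'   sub-directory per repetition; default a session temp dir).
#' @return a data.frame with one row per repetition: `rep`,
#'   `single_session`, `intertwined`, `gap`.
#' @export
measurement_bias_experiment <- function(cfg, n_reps = 10, block = c(2, 2),
                                        train_fraction = 10 / 11,
                                        seed = 1L,
                                        dir = tempfile("biasrep")) {
  rows <- lapply(seq_len(n_reps), function(r) {
    cfg$master_seed <- derive_seed(seed, "bias-rep", r)
    d <- file.path(dir, sprintf("rep%02d", r))
    manifest <- generate_dataset(cfg, d)
    fs <- build_features(manifest, cfg$optics$sensor, dir = d,
                         block = block)
    # single session: average the per-session within-session accuracy
    single <- mean(vapply(sort(unique(fs$sessions)), function(s) {
      sp <- split_single_session(manifest, s,
                                 train_fraction = train_fraction,
                                 seed = derive_seed(cfg$master_seed,
                                                    "ss", s))
      accuracy(fit_and_score(fs, manifest_rows(manifest, sp$train),
                             manifest_rows(manifest, sp$test)))
    }, numeric(1)))
    inter <- loso_accuracy(fs)$accuracy
    unlink(d, recursive = TRUE)
    data.frame(rep = r, single_session = single, intertwined = inter,
               gap = single - inter)
  })
  do.call(rbind, rows)
}

#' Compare diffuser grits on simulated recordings
#'
#' For each of `n_seeds` seeded repetitions, generates one dataset per
#' grit grade with the SAME repetition seed (a paired design: the same
#' particle stream recorded through different glasses, as when diffuser
#' order is randomised across sessions), scores each with the
#' intertwined protocol, and reports the mean accuracy per grit — the
#' simulated analogue of comparing ground-glass diffusers in the
#' physical setup.
#'
#' @param cfg a [simulation_config()] template.
#' @param grits character vector of grit grades.
#' @param n_seeds independent repetitions per grit.
#' @param block OR-pooling block for feature building.
#' @param envelope_scale multiplier applied to the default per-grit
#'   envelope widths; use it to keep the envelope proportional when the
#'   sensor is scaled down (e.g. 0.25 for a quarter-size sensor).
#' @param seed master seed.
#' @param dir scratch directory.
#' @return a data.frame with columns `grit`, `seed_rep`, `accuracy`,
#'   plus the per-grit mean in attribute `summary`.
#' @export
compare_diffusers <- function(cfg, grits = c("none", "120", "600", "1500"),
                              n_seeds = 5, block = c(2, 2),
                              envelope_scale = 1, seed = 1L,
                              dir = tempfile("diffuser")) {
  rows <- list()
  for (g in grits) {
    cfg$diffuser <- diffuser_config(g, seed = derive_seed(seed, "glass", g))
    cfg$diffuser$envelope_sigma <- cfg$diffuser$envelope_sigma *
      envelope_scale
    for (r in seq_len(n_seeds)) {
      # repetition seed shared across grits: paired comparison
      cfg$master_seed <- derive_seed(seed, "diffuser-rep", r)
      d <- file.path(dir, sprintf("grit%s_rep%02d", g, r))
      manifest <- generate_dataset(cfg, d)
      fs <- build_features(manifest, cfg$optics$sensor, dir = d,
                           block = block)
      acc <- loso_accuracy(fs)$accuracy
      unlink(d, recursive = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(grit = g, seed_rep = r,
                                              accuracy = acc)
    }
  }
  res <- do.call(rbind, rows)
  summ <- stats::aggregate(accuracy ~ grit, res, mean)
  summ <- summ[match(grits, summ$grit), ]
  rownames(summ) <- NULL
  attr(res, "summary") <- summ
  res
}
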