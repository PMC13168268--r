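#' Hypervector encoder configuration
#'
#' Binary features enter the classifier either unchanged (`"identity"`,
#' the hypervector dimension D equals the feature length: the optical
#' pattern itself is the high-dimensional code) or through `"subsample"`,
#' which keeps a fixed random subset of D feature positions — the prefix
#' of a seeded permutation, drawn once and frozen for the life of a
#' model. Subsampling makes a conventional dimension such as D = 10,000
#' available when the pixel feature is longer.
#'
#' @param D hypervector dimension. Defaults to `feature_length`.
#' @param mode `"identity"` or `"subsample"`.
#' @param feature_length length of the incoming feature vectors.
#' @param seed integer seed for the subsampling permutation (ignored in
#'   identity mode).
#' @return an object of class `hdc_encoder`.
#' @export
#' @examples
#' enc <- hdc_encoder(feature_length = 614400, D = 10000, mode = "subsample")
#' enc$D
hdc_encoder <- function(feature_length, D = feature_length,
                        mode = c("identity", "subsample"), seed = 1L) {
  mode <- match.arg(mode)
  feature_length <- as.integer(feature_length)
  D <- as.integer(D)
  if (mode == "identity" && D != feature_length) {
    stop("identity encoder requires D == feature_length (got D = ", D,
         ", feature_length = ", feature_length, ")")
  }
  if (mode == "subsample" && D > feature_length) {
    stop("subsample encoder requires D <= feature_length")
  }
  idx <- if (mode == "subsample") {
    with_seed(seed, sample.int(feature_length))[seq_len(D)]
  } else NULL
  structure(list(D = D, mode = mode, feature_length = feature_length,
                 seed = as.integer(seed), idx = idx),
            class = "hdc_encoder")
}

#' Encode binary features into hypervectors
#'
#' @param features integer 0/1 vector of length `feature_length`, or an
#'   `n x feature_length` matrix (one feature per row).
#' @param encoder an [hdc_encoder()].
#' @return 0/1 vector of length D, or an `n x D` matrix.
#' @export
hdc_encode <- function(features, encoder) {
  stopifnot(inherits(encoder, "hdc_encoder"))
  vec <- !is.matrix(features)
  m <- if (vec) matrix(as.integer(features), nrow = 1) else features
  if (ncol(m) != encoder$feature_length) {
    stop("feature length ", ncol(m), " does not match encoder (",
         encoder$feature_length, ")")
  }
  out <- if (encoder$mode == "identity") m else m[, encoder$idx, drop = FALSE]
  if (vec) as.integer(out[1, ]) else out
}

#' Hamming distance between binary hypervectors
#'
#' The number of positions at which two equal-length binary vectors
#' differ: `sum(A != B)`. It is 0 iff the vectors are equal, and for two
#' independent uniform random vectors of dimension D it concentrates
#' around `0.5 * D`.
#'
#' @param a,b 0/1 vectors of equal length.
#' @return non-negative integer count.
#' @export
#' @examples
#' hamming_distance(c(0, 0, 0, 0), c(1, 1, 1, 1)) # 4
hamming_distance <- function(a, b) {
  if (length(a) != length(b)) {
    stop("dimension mismatch: ", length(a), " vs ", length(b))
  }
  sum(a != b)
}

# All pairwise Hamming distances between rows of binary matrices
# A (n x D) and B (m x D), via the bilinear identity
# Ham = |a| + |b| - 2 a.b. Returns an n x m matrix.
hamming_cross <- function(A, B) {
  if (ncol(A) != ncol(B)) stop("dimension mismatch")
  ra <- rowSums(A)
  rb <- rowSums(B)
  outer(ra, rb, "+") - 2 * tcrossprod(A, B)
}

#' Bundle hypervectors into a prototype by bitwise majority voting
#'
#' Position by position, the prototype takes the bit value occurring most
#' often among the bundled vectors. With an even number of vectors a
#' position can tie; ties are resolved by a tie-break hypervector drawn
#' once from `tie_seed`, so training stays deterministic and independent
#' of sample order.
#'
#' @param hvs list of equal-length 0/1 vectors, or an `n x D` 0/1 matrix
#'   with one hypervector per row.
#' @param tie_seed integer seed for the tie-break vector.
#' @return 0/1 integer vector of length D.
#' @export
#' @examples
#' hdc_bundle(rbind(c(0, 1, 1), c(1, 0, 1), c(1, 1, 0))) # 1 1 1
hdc_bundle <- function(hvs, tie_seed = 1L) {
  if (is.list(hvs)) {
    if (!length(hvs)) stop("cannot bundle an empty set of hypervectors")
    if (length(unique(lengths(hvs))) != 1) {
      stop("hypervectors have unequal dimensions")
    }
    hvs <- do.call(rbind, hvs)
  }
  if (!is.matrix(hvs) || nrow(hvs) == 0) {
    stop("cannot bundle an empty set of hypervectors")
  }
  n <- nrow(hvs)
  ones <- colSums(hvs)
  out <- as.integer(2 * ones > n)
  tied <- 2 * ones == n
  if (any(tied)) {
    tb <- tie_break_vector(ncol(hvs), tie_seed)
    out[tied] <- tb[tied]
  }
  out
}

tie_break_vector <- function(D, tie_seed) {
  with_seed(tie_seed, sample(c(0L, 1L), D, replace = TRUE))
}

#' Train a hyperdimensional classifier
#'
#' Single-pass prototype learning: every training feature is encoded to a
#' hypervector and, per class, the hypervectors are bundled by bitwise
#' majority voting ([hdc_bundle()]) into one class prototype. There is no
#' iteration and no gradient; the model is a deterministic function of
#' the sample set, the encoder and the tie seed (sample order does not
#' matter).
#'
#' @param features `n x L` integer 0/1 matrix, one training feature per
#'   row.
#' @param labels character or factor vector of length `n`.
#' @param encoder an [hdc_encoder()]; default is the identity encoder at
#'   the feature length.
#' @param tie_seed integer seed for majority tie-breaking.
#' @return an object of class `hdc_model` with the encoder, per-class
#'   prototype matrix (rows in sorted label order), per-class sample
#'   counts `n_samples`, and `tie_seed`.
#' @export
#' @examples
#' f <- rbind(c(1, 1, 0, 0), c(1, 0, 0, 0), c(0, 0, 1, 1), c(0, 1, 1, 1))
#' m <- hdc_train(f, c("A", "A", "B", "B"))
#' hdc_classify(m, c(1, 1, 0, 1))$label
hdc_train <- function(features, labels, encoder = NULL, tie_seed = 1L) {
  stopifnot(is.matrix(features), nrow(features) == length(labels))
  labels <- as.character(labels)
  if (anyNA(labels)) stop("labels must not contain NA")
  if (is.null(encoder)) encoder <- hdc_encoder(ncol(features))
  classes <- sort(unique(labels))
  enc <- hdc_encode(features, encoder)
  protos <- matrix(0L, nrow = length(classes), ncol = encoder$D,
                   dimnames = list(classes, NULL))
  n_samples <- integer(length(classes))
  for (i in seq_along(classes)) {
    rows <- which(labels == classes[i])
    if (!length(rows)) stop("class ", classes[i], " has no training samples")
    protos[i, ] <- hdc_bundle(enc[rows, , drop = FALSE], tie_seed = tie_seed)
    n_samples[i] <- length(rows)
  }
  structure(list(encoder = encoder, labels = classes, prototypes = protos,
                 n_samples = stats::setNames(n_samples, classes),
                 tie_seed = as.integer(tie_seed)),
            class = "hdc_model")
}

#' @export
print.hdc_model <- function(x, ...) {
  cat(sprintf("<hdc_model> %d classes (%s), D = %d, encoder = %s\n",
              length(x$labels), paste(x$labels, collapse = ", "),
              x$encoder$D, x$encoder$mode))
  cat("  samples per class:",
      paste(sprintf("%s=%d", x$labels, x$n_samples), collapse = ", "), "\n")
  invisible(x)
}

#' Classify features by nearest prototype in Hamming distance
#'
#' Each query feature is encoded with the model's encoder and assigned to
#' the class whose prototype hypervector is nearest in Hamming distance
#' (argmin over classes). Ties go to the lexicographically smallest class
#' label, deterministically.
#'
#' @param model an [hdc_train()] model.
#' @param features 0/1 vector or `n x L` matrix of query features.
#' @return for a single feature, a list with `label` and the named
#'   `distances` vector; for a matrix, a list with character vector
#'   `labels` and the `n x classes` `distances` matrix.
#' @export
hdc_classify <- function(model, features) {
  stopifnot(inherits(model, "hdc_model"))
  vec <- !is.matrix(features)
  m <- if (vec) matrix(as.integer(features), nrow = 1) else features
  q <- hdc_encode(m, model$encoder)
  d <- hamming_cross(q, model$prototypes)
  colnames(d) <- model$labels
  # prototypes are stored in sorted label order, so "first" implements
  # the smallest-label tie rule
  pick <- max.col(-d, ties.method = "first")
  labs <- model$labels[pick]
  if (vec) list(label = labs[1], distances = d[1, ])
  else list(labels = labs, distances = d)
}

#' Save / load a hyperdimensional classifier model
#'
#' The on-disk model is a JSON document holding the encoder
#' configuration, tie seed, class labels, per-class sample counts and the
#' prototype bit vectors packed as hexadecimal strings (4 bits per
#' character, most significant bit first, zero-padded at the tail).
#'
#' @param model an `hdc_model`.
#' @param path file path (conventionally `.json`).
#' @return `read_hdc_model()` returns the model; `write_hdc_model()`
#'   returns `path` invisibly.
#' @export
write_hdc_model <- function(model, path) {
  stopifnot(inherits(model, "hdc_model"))
  obj <- list(
    format = "hdflow-model",
    version = 1L,
    encoder = list(D = model$encoder$D, mode = model$encoder$mode,
                   feature_length = model$encoder$feature_length,
                   seed = model$encoder$seed),
    tie_seed = model$tie_seed,
    labels = model$labels,
    n_samples = as.integer(model$n_samples),
    prototypes = apply(model$prototypes, 1, pack_bits_hex)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_hdc_model
#' @export
read_hdc_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "hdflow-model")) {
    stop("'", path, "' is not an hdflow model file")
  }
  enc <- hdc_encoder(feature_length = obj$encoder$feature_length,
                     D = obj$encoder$D, mode = obj$encoder$mode,
                     seed = obj$encoder$seed)
  protos <- t(vapply(obj$prototypes, unpack_bits_hex, integer(enc$D),
                     n = enc$D))
  dimnames(protos) <- list(obj$labels, NULL)
  structure(list(encoder = enc, labels = obj$labels, prototypes = protos,
                 n_samples = stats::setNames(as.integer(obj$n_samples),
                                             obj$labels),
                 tie_seed = as.integer(obj$tie_seed)),
            class = "hdc_model")
}

# Pack a 0/1 vector into a hex string, 4 bits per character, MSB first;
# the final nibble is zero-padded.
pack_bits_hex <- function(bits) {
  n <- length(bits)
  pad <- (4 - n %% 4) %% 4
  b <- c(as.integer(bits), integer(pad))
  nib <- b[c(TRUE, FALSE, FALSE, FALSE)] * 8L +
    b[c(FALSE, TRUE, FALSE, FALSE)] * 4L +
    b[c(FALSE, FALSE, TRUE, FALSE)] * 2L +
    b[c(FALSE, FALSE, FALSE, TRUE)]
  paste(c("0", "1", "2", "3", "4", "5", "6", "7", "8", "9",
          "a", "b", "c", "d", "e", "f")[nib + 1L], collapse = "")
}

unpack_bits_hex <- function(hex, n) {
  nib <- match(strsplit(hex, "")[[1]],
               c("0", "1", "2", "3", "4", "5", "6", "7", "8", "9",
                 "a", "b", "c", "d", "e", "f")) - 1L
  bits <- as.integer(rbind(nib %/% 8L, (nib %/% 4L) %% 2L,
                           (nib %/% 2L) %% 2L, nib %% 2L))
  bits[seq_len(n)]
}
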