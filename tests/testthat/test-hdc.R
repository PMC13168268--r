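test_that("identity encoding returns the feature bits unchanged", {
  enc <- hdc_encoder(4)
  expect_equal(hdc_encode(c(1L, 0L, 0L, 1L), enc), c(1L, 0L, 0L, 1L))
  expect_error(hdc_encoder(4, D = 3), "identity")
  expect_error(hdc_encode(c(1L, 0L), enc), "does not match")
})

test_that("subsampling keeps a frozen seeded permutation prefix", {
  enc <- hdc_encoder(1000, D = 64, mode = "subsample", seed = 5)
  x <- random_bits(1000, seed = 2)
  out <- hdc_encode(x, enc)
  expect_length(out, 64)
  # recompute the permutation prefix independently
  idx <- withr::with_seed(5L, sample.int(1000))[1:64]
  expect_equal(out, x[idx])
  # same seed -> same encoder; different seed -> different subset
  expect_equal(hdc_encode(x, hdc_encoder(1000, D = 64, "subsample",
                                         seed = 5)), out)
  enc2 <- hdc_encoder(1000, D = 64, mode = "subsample", seed = 6)
  expect_false(identical(hdc_encode(x, enc2), out))
  expect_error(hdc_encoder(10, D = 11, mode = "subsample"), "D <=")
})

test_that("Hamming distance matches the exhaustive oracle at small D", {
  for (n in c(2, 4, 6)) {
    vs <- all_bitvectors(n)
    for (i in seq_len(nrow(vs))) {
      for (j in seq_len(nrow(vs))) {
        expect_identical(hamming_distance(vs[i, ], vs[j, ]),
                         hamming_oracle(vs[i, ], vs[j, ]))
      }
    }
  }
  expect_equal(hamming_distance(c(0, 0, 0, 0), c(1, 1, 1, 1)), 4)
  expect_error(hamming_distance(c(0, 1), c(0, 1, 1)), "mismatch")
})

test_that("Hamming distance is a metric on random hypervectors", {
  for (seed in 1:20) {
    a <- random_bits(128, seed)
    b <- random_bits(128, seed + 100)
    c_ <- random_bits(128, seed + 200)
    expect_gte(hamming_distance(a, b), 0)
    expect_equal(hamming_distance(a, a), 0)
    expect_equal(hamming_distance(a, b), hamming_distance(b, a))
    expect_lte(hamming_distance(a, c_),
               hamming_distance(a, b) + hamming_distance(b, c_))
    if (hamming_distance(a, b) == 0) expect_identical(a, b)
  }
})

test_that("pairwise Hamming via the bilinear identity matches per-pair sums", {
  A <- random_bit_matrix(7, 50, seed = 1)
  B <- random_bit_matrix(4, 50, seed = 2)
  d <- hdflow:::hamming_cross(A, B)
  for (i in 1:7) {
    for (j in 1:4) expect_equal(d[i, j], hamming_oracle(A[i, ], B[j, ]))
  }
})

test_that("majority bundling agrees with the counting oracle", {
  expect_equal(hdc_bundle(rbind(c(0, 1, 1), c(1, 0, 1), c(1, 1, 0))),
               c(1L, 1L, 1L))
  v <- random_bits(40, seed = 3)
  expect_equal(hdc_bundle(matrix(v, nrow = 1)), v) # singleton identity

  for (seed in 1:25) {
    m <- random_bit_matrix(withr::with_seed(seed, sample(2:9, 1)), 64,
                           seed = seed)
    tie <- hdflow:::tie_break_vector(64, 11L)
    expect_equal(hdc_bundle(m, tie_seed = 11L), majority_oracle(m, tie))
  }
})

test_that("tied positions are resolved by the tie-break vector", {
  m <- rbind(c(0L, 1L), c(1L, 0L)) # both positions tied 1-1
  tie <- hdflow:::tie_break_vector(2, 3L)
  expect_equal(hdc_bundle(m, tie_seed = 3L), tie)
})

test_that("bundling is invariant to input order and accepts lists", {
  m <- random_bit_matrix(9, 80, seed = 6)
  perm <- withr::with_seed(7, sample(9))
  expect_equal(hdc_bundle(m), hdc_bundle(m[perm, ]))
  expect_equal(hdc_bundle(asplit(m, 1)), hdc_bundle(m))
  expect_error(hdc_bundle(list()), "empty")
  expect_error(hdc_bundle(list(c(0L, 1L), c(0L, 1L, 1L))), "unequal")
})

test_that("training builds one majority prototype per class in one pass", {
  f <- rbind(random_bit_matrix(6, 32, 1), random_bit_matrix(7, 32, 2))
  labels <- c(rep("B", 6), rep("A", 7))
  model <- hdc_train(f, labels, tie_seed = 4L)
  expect_equal(model$labels, c("A", "B")) # sorted
  expect_equal(unname(model$n_samples), c(7L, 6L))
  tie <- hdflow:::tie_break_vector(32, 4L)
  expect_equal(unname(model$prototypes["B", ]),
               majority_oracle(f[1:6, ], tie))
  # order invariance: retrain on a shuffled sample list
  perm <- withr::with_seed(5, sample(13))
  model2 <- hdc_train(f[perm, ], labels[perm], tie_seed = 4L)
  expect_equal(model2$prototypes, model$prototypes)
  # one sample per class: the prototype is the sample itself
  m1 <- hdc_train(f[c(1, 7), ], c("X", "Y"))
  expect_equal(unname(m1$prototypes["X", ]), f[1, ])
})

test_that("uniform odd duplication of the training set leaves prototypes unchanged", {
  f <- random_bit_matrix(5, 40, seed = 8) # odd class size
  labels <- rep("A", 5)
  base <- hdc_train(f, labels, tie_seed = 1L)
  trip <- hdc_train(f[rep(1:5, 3), ], rep("A", 15), tie_seed = 1L)
  expect_equal(trip$prototypes, base$prototypes)
})

test_that("classification is argmin of Hamming with lexicographic ties", {
  protos <- rbind(A = c(1L, 1L, 1L, 1L), B = c(0L, 0L, 0L, 0L))
  model <- structure(list(encoder = hdc_encoder(4), labels = c("A", "B"),
                          prototypes = protos,
                          n_samples = c(A = 1L, B = 1L), tie_seed = 1L),
                     class = "hdc_model")
  r <- hdc_classify(model, c(1L, 1L, 1L, 0L))
  expect_equal(r$label, "A")
  expect_equal(unname(r$distances), c(1, 3))
  # query equal to a prototype: distance zero
  r0 <- hdc_classify(model, c(0L, 0L, 0L, 0L))
  expect_equal(r0$label, "B")
  expect_equal(unname(r0$distances["B"]), 0)
  # equidistant query: smaller label wins
  rt <- hdc_classify(model, c(1L, 1L, 0L, 0L))
  expect_equal(unname(rt$distances), c(2, 2))
  expect_equal(rt$label, "A")
})

test_that("training samples whose encoding equals the prototype classify home", {
  f <- random_bit_matrix(12, 64, seed = 10)
  labels <- rep(c("A", "B", "C"), each = 4)
  model <- hdc_train(f, labels)
  for (lab in model$labels) {
    r <- hdc_classify(model, model$prototypes[lab, ])
    expect_equal(r$label, lab)
    expect_equal(unname(r$distances[lab]), 0)
  }
})

test_that("hex bit packing round-trips arbitrary lengths", {
  for (n in c(1, 4, 7, 8, 13, 64, 100)) {
    bits <- random_bits(n, seed = n)
    hex <- hdflow:::pack_bits_hex(bits)
    expect_equal(nchar(hex), ceiling(n / 4))
    expect_equal(hdflow:::unpack_bits_hex(hex, n), bits)
  }
  expect_equal(hdflow:::pack_bits_hex(c(1, 0, 0, 1, 1, 1, 1, 1)), "9f")
})

test_that("model files round-trip through the JSON container", {
  f <- rbind(random_bit_matrix(10, 300, 1), random_bit_matrix(10, 300, 2))
  labels <- rep(c("A", "B"), each = 10)
  enc <- hdc_encoder(300, D = 120, mode = "subsample", seed = 9)
  model <- hdc_train(f, labels, encoder = enc, tie_seed = 13L)
  path <- withr::local_tempfile(fileext = ".json")
  write_hdc_model(model, path)
  back <- read_hdc_model(path)
  expect_equal(back$prototypes, model$prototypes)
  expect_equal(back$encoder$idx, model$encoder$idx)
  expect_equal(back$n_samples, model$n_samples)
  expect_equal(back$tie_seed, model$tie_seed)
  # the reloaded model classifies identically
  q <- random_bit_matrix(5, 300, seed = 3)
  expect_equal(hdc_classify(back, q)$labels, hdc_classify(model, q)$labels)
})
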