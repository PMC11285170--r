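test_that("binarization keeps prevalent peaks and maps counts to 0/1", {
  x <- cbind(c(0, 3, 0, 0, 0),   # nonzero in 1 of 5 cells -> kept (threshold 1)
             c(0, 0, 0, 0, 0),   # all-zero -> removed
             c(2, 1, 0, 5, 0))
  ds <- make_atac(x)
  out <- binarize_and_filter(ds, 0.001)
  expect_equal(ncol(out$matrix), 2L)
  expect_equal(out$feature_ids, ds$feature_ids[c(1, 3)])
  expect_equal(out$matrix[, 1], c(0, 1, 0, 0, 0))
  expect_equal(out$matrix[, 2], c(1, 1, 0, 1, 0))
})

test_that("prevalence threshold is max(1, ceiling(fraction * N)) cells", {
  # 2000 cells, fraction 0.001 -> threshold ceil(2) = 2 cells
  x <- matrix(0, 2000, 2)
  x[1, 1] <- 4            # nonzero in exactly 1 cell -> removed
  x[c(7, 1900), 2] <- 1   # nonzero in 2 cells -> kept
  out <- binarize_and_filter(make_atac(x), 0.001)
  expect_equal(out$feature_ids, make_atac(x)$feature_ids[2])
})

test_that("binarization is idempotent and filtering matches brute-force recount", {
  set.seed(71)
  for (i in 1:10) {
    n <- sample(20:60, 1)
    m <- sample(10:30, 1)
    frac <- sample(c(0.001, 0.05, 0.2), 1)
    x <- matrix(rpois(n * m, 0.2), n, m)
    if (all(colSums(x) == 0)) x[1, 1] <- 1
    ds <- make_atac(x)
    out <- tryCatch(binarize_and_filter(ds, frac), error = function(e) NULL)
    thr <- max(1, ceiling(frac * n))
    keep_brute <- which(colSums(x > 0) >= thr)
    if (length(keep_brute) == 0) {
      expect_null(out)
      next
    }
    expect_equal(out$feature_ids, ds$feature_ids[keep_brute])
    twice <- binarize_and_filter(out, frac)
    expect_identical(as.matrix(twice$matrix), as.matrix(out$matrix))
    expect_true(all(colSums(out$matrix > 0) >= thr))
  }
})

test_that("binarize_and_filter rejects empty input and all-filtered output", {
  expect_error(binarize_and_filter(make_atac(matrix(0, 5, 2)), 0.9),
               "below the prevalence threshold")
  x0 <- matrix(numeric(0), 0, 0)
  expect_error(raw_dataset(x0, character(), character(), modality = "atac") |>
                 binarize_and_filter(), "empty")
})

test_that("highly variable selection ranks by variance with a deterministic tie rule", {
  # open fraction 0.5 has maximal Bernoulli variance; 0.01 minimal
  x <- cbind(rep(c(0, 1), 50), c(1, rep(0, 99)))
  ds <- make_atac(x)
  sel <- select_highly_variable(ds, 1)
  expect_equal(sel$feature_ids, ds$feature_ids[1])

  # n_features >= available -> identity
  sel_all <- select_highly_variable(ds, 10)
  expect_equal(sel_all$feature_ids, ds$feature_ids)

  # exact tie -> lower original column index wins
  xt <- cbind(rep(c(0, 1), 10), rep(c(1, 0), 10), rep(c(0, 1), 10))
  tie <- select_highly_variable(make_atac(xt), 2)
  expect_equal(tie$feature_ids, make_atac(xt)$feature_ids[1:2])
})

test_that("top-n highly variable sets are nested in top-(n+1) sets", {
  set.seed(42)
  x <- matrix(rbinom(50 * 20, 1, runif(20)[rep(1:20, each = 50)]), 50, 20)
  ds <- make_atac(x)
  prev <- character(0)
  for (n in 1:20) {
    cur <- select_highly_variable(ds, n)$feature_ids
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("RNA normalization scales cells to the size factor then log1p", {
  x <- rbind(c(100, 900), c(5000, 5000))
  ds <- raw_dataset(x, c("g1", "g2"), c("cellA", "cellB"), modality = "rna")
  out <- normalize_rna(ds, 1e4)
  expect_equal(out$matrix[1, ], c(log(1001), log(9001)), tolerance = 1e-12)
  # cell already at the size factor: only log1p applied
  expect_equal(out$matrix[2, ], log1p(c(5000, 5000)), tolerance = 1e-12)
})

test_that("RNA normalization errors on zero-count cells, naming them", {
  x <- rbind(c(1, 2), c(0, 0))
  ds <- raw_dataset(x, c("g1", "g2"), c("ok", "empty_cell"), modality = "rna")
  expect_error(normalize_rna(ds), "empty_cell")
})

test_that("RNA normalization preserves within-cell rank order", {
  set.seed(9)
  x <- matrix(rpois(5 * 30, 5) + 1, 5, 30)
  ds <- raw_dataset(x, sprintf("g%d", 1:30), sprintf("c%d", 1:5),
                    modality = "rna")
  out <- normalize_rna(ds)
  for (i in 1:5) expect_equal(order(out$matrix[i, ]), order(x[i, ]))
})

test_that("peak remapping sums overlapping source counts per target peak", {
  # identical peak sets -> identity
  x <- matrix(1:6, 2, 3)
  ds <- make_atac(x, peaks = c("chr1:0-10", "chr1:20-30", "chr2:0-10"))
  out <- remap_source_to_target_peaks(ds, ds$feature_ids)
  expect_matrix_equal(out$matrix, x)

  # overlap: source chr1:100-200 (counts) overlaps target chr1:150-250
  ds2 <- make_atac(matrix(c(2, 7), 2, 1), peaks = "chr1:100-200")
  out2 <- remap_source_to_target_peaks(ds2, "chr1:150-250")
  expect_equal(as.vector(out2$matrix), c(2, 7))

  # target peak on an absent chromosome -> zero column; adjacent half-open
  # intervals (end == start) do not overlap
  out3 <- remap_source_to_target_peaks(ds2, c("chrX:0-100", "chr1:200-300"))
  expect_true(all(out3$matrix == 0))

  # multiple overlapping source peaks are summed
  ds4 <- make_atac(matrix(c(1, 2, 3, 4), 1), peaks = c(
    "chr1:0-50", "chr1:40-80", "chr1:100-120", "chr2:0-50"))
  out4 <- remap_source_to_target_peaks(ds4, "chr1:30-110")
  expect_equal(as.vector(out4$matrix), 1 + 2 + 3)

  expect_error(remap_source_to_target_peaks(ds2, "chr1_100_200"),
               "chr1_100_200")
})

test_that("feature alignment restricts both datasets to common features in source order", {
  x <- matrix(rbinom(40, 1, 0.5), 4, 10)
  src <- make_atac(x)
  psrc <- select_highly_variable(binarize_and_filter(src), 10)
  ptgt <- psrc
  ptgt$matrix <- ptgt$matrix[, 10:1]
  ptgt$feature_ids <- rev(ptgt$feature_ids)
  al <- align_features(psrc, subset_target <- ptgt)
  expect_equal(al$source$feature_ids, al$target$feature_ids)
  expect_matrix_equal(al$source$matrix[, al$source$feature_ids == psrc$feature_ids[3]],
                      al$target$matrix[, al$target$feature_ids == psrc$feature_ids[3]])

  disj <- ptgt
  disj$feature_ids <- paste0("other_", seq_along(ptgt$feature_ids))
  expect_error(align_features(psrc, disj), "no common features")
})

test_that("preprocess_pair produces aligned binary matrices", {
  tp <- tiny_pair(seed = 3)
  expect_identical(tp$pp$source$feature_ids, tp$pp$target$feature_ids)
  expect_true(all(as.matrix(tp$pp$source$matrix) %in% c(0, 1)))
  expect_s3_class(tp$pp$source, "processed_dataset")
})
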