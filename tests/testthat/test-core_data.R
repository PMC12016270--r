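test_that("normalize_counts rescales each cell to 10k and log-transforms", {
  m <- rbind(c(1, 3), c(5000, 5000))
  ds <- perturb_dataset(m, c("ctrl", "gA"), gene_names = c("gA", "gB"))
  norm <- normalize_counts(ds)
  # direct arithmetic: [1,3] -> [2500, 7500] -> log(2501), log(7501)
  expect_equal(norm$matrix[1, ], c(gA = log(2501), gB = log(7501)))
  # total already 10000: scale factor 1
  expect_equal(norm$matrix[2, ], c(gA = log(5001), gB = log(5001)))
  expect_true(norm$normalized)
  expect_error(normalize_counts(norm), "already")
})

test_that("zero-total cells are dropped with a warning; all-zero errors", {
  m <- rbind(c(0, 0), c(2, 2), c(1, 0))
  ds <- perturb_dataset(m, c("gA", "ctrl", "ctrl"), gene_names = c("gA", "gB"))
  expect_warning(norm <- normalize_counts(ds), "zero total")
  expect_equal(nrow(norm$matrix), 2L)
  expect_equal(attr(norm, "dropped_cells"), 1L)
  all_zero <- perturb_dataset(matrix(0, 2, 2), c("ctrl", "gA"),
                              gene_names = c("gA", "gB"))
  expect_error(normalize_counts(all_zero), "empty dataset after filtering")
})

test_that("perturb_dataset validates its invariants", {
  m <- matrix(1, 2, 2)
  expect_error(perturb_dataset(m, c("ctrl", "gX"), gene_names = c("gA", "gB")),
               "unknown gene")
  expect_error(perturb_dataset(m, c("gA", "gB"), gene_names = c("gA", "gB")),
               "control")
  expect_error(perturb_dataset(m, c("ctrl", "gA"), gene_names = c("gA", "gA")),
               "unique")
  expect_error(perturb_dataset(m * -1, c("ctrl", "gA"), gene_names = c("gA", "gB")),
               "non-negative")
  combo <- perturb_dataset(m, c("ctrl", "gA+gB"), gene_names = c("gA", "gB"))
  expect_equal(combo$targets[["gA+gB"]], c("gA", "gB"))
})

test_that("pseudobulk equals a brute-force group-by mean", {
  ds <- toy_dataset()
  pb <- pseudobulk(ds)
  for (cond in unique(ds$conditions)) {
    expect_equal(pb[cond, ],
                 colMeans(ds$matrix[ds$conditions == cond, , drop = FALSE]),
                 info = cond)
  }
  expect_equal(pb["ctrl", ], c(gA = 1, gB = 2, gC = 1, gD = 1))
  # single cell per condition: the row is that cell
  one <- perturb_dataset(rbind(c(1, 2), c(3, 4)), c("ctrl", "gA"),
                         gene_names = c("gA", "gB"), normalized = TRUE)
  expect_equal(pseudobulk(one)["gA", ], c(gA = 3, gB = 4))
  expect_error(pseudobulk(perturb_dataset(rbind(c(1, 2), c(3, 4)),
                                          c("ctrl", "gA"),
                                          gene_names = c("gA", "gB"))),
               "log-normalized")
})

test_that("delta profiles are pseudobulk minus control and reconstruct exactly", {
  ds <- toy_dataset()
  pb <- pseudobulk(ds)
  d <- delta_profiles(pb, "ctrl")
  expect_false("ctrl" %in% rownames(d))
  for (p in rownames(d)) {
    expect_equal(d[p, ], pb[p, ] - pb["ctrl", ], info = p)
    expect_equal(d[p, ] + pb["ctrl", ], pb[p, ]) # exact reconstruction
  }
  expect_error(delta_profiles(pb, "nope"), "control label")
  # equal rows give a zero delta
  pb2 <- rbind(ctrl = c(1, 1, 1), gA = c(1, 1, 1), gB = c(2, 0, 1))
  d2 <- delta_profiles(pb2, "ctrl")
  expect_equal(unname(d2["gA", ]), c(0, 0, 0))
  expect_equal(unname(d2["gB", ]), c(1, -1, 0))
})

test_that("make_split is a deterministic disjoint partition", {
  perts <- sprintf("p%02d", 1:10)
  s <- make_split(perts, fractions = c(train = 0.8, validation = 0.1, test = 0.1),
                  seed = 3)
  expect_length(s$train, 8L)
  expect_length(s$validation, 1L)
  expect_length(s$test, 1L)
  expect_identical(make_split(perts, c(train = 0.8, validation = 0.1, test = 0.1),
                              seed = 3), s)
  for (seed in 1:5) {
    sp <- make_split(perts, seed = seed)
    all_labels <- c(sp$train, sp$validation, sp$test)
    expect_equal(sort(all_labels), sort(perts))   # coverage
    expect_equal(anyDuplicated(all_labels), 0L)   # disjointness
  }
  expect_error(make_split(c("a", "b")), "at least")
})

test_that("label_subgroup matches the combo_seen definitions", {
  train <- c("A", "C", "D+E")
  expect_equal(label_subgroup("F+G", train), "combo_seen0")
  expect_equal(label_subgroup("A+G", train), "combo_seen1")
  expect_equal(label_subgroup("A+C", train), "combo_seen2")
  expect_equal(label_subgroup("B", train), "unseen_single")
  expect_equal(label_subgroup("A", train), "seen_single")
  # gene seen only inside a train combo still counts for singles...
  expect_equal(label_subgroup("D", train), "seen_single")
  # ...but not as a "seen single" component of a test combo
  expect_equal(label_subgroup("D+C", train), "combo_seen1")
  expect_error(label_subgroup("A+B+C", train), "more than 2")
})

test_that("dense CSV round-trips a dataset", {
  ds <- toy_dataset(normalized = FALSE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_perturb_csv(ds, path)
  back <- read_perturb_csv(path)
  expect_equal(back$matrix, ds$matrix)
  expect_equal(back$conditions, ds$conditions)
  expect_equal(back$targets, ds$targets)
})
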