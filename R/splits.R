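#' Perturbation-exclusive train/validation/test split
#'
#' Partitions perturbation *labels* (not cells) into disjoint train,
#' validation and test sets, so every test perturbation — or test combo — is
#' unseen during training. Combos are assigned as whole labels. The split is
#' a deterministic function of `seed`: labels are shuffled once with R's
#' default Mersenne-Twister generator under the given seed and then cut into
#' contiguous blocks.
#'
#' Set sizes are `floor(fraction * n)` with any remainder assigned to the
#' training set; a set with a positive fraction is guaranteed at least one
#' label (taken from the largest set) so that requested sets are never empty.
#'
#' @param perturbations Character vector of perturbation labels.
#' @param fractions Named numeric vector `c(train=, validation=, test=)`,
#'   positive, summing to at most 1.
#' @param seed Integer seed; the split is reproducible given this value.
#' @param combo_sep Separator used to parse combo labels for subgroup tags.
#' @return A `split_spec`: list with `train`, `validation`, `test` label
#'   vectors, `subgroups` (named character vector tagging each test label,
#'   see [label_subgroup()]), and `seed`.
#' @export
make_split <- function(perturbations,
                       fractions = c(train = 0.75, validation = 0.1, test = 0.15),
                       seed = 1L, combo_sep = "+") {
  perturbations <- unique(as.character(perturbations))
  n <- length(perturbations)
  stopifnot(length(fractions) == 3L, all(fractions > 0), sum(fractions) <= 1 + 1e-12)
  if (is.null(names(fractions))) names(fractions) <- c("train", "validation", "test")
  if (n < 3L) stop("need at least as many perturbations as sets (3)")
  shuffled <- withr::with_seed(seed, sample(perturbations))
  sizes <- floor(fractions * n)
  sizes["train"] <- sizes["train"] + (n - sum(sizes)) * (sum(fractions) >= 1 - 1e-12)
  # guarantee non-empty sets: borrow from the largest
  for (s in names(sizes)) {
    while (sizes[s] == 0L) {
      donor <- names(which.max(sizes))
      sizes[donor] <- sizes[donor] - 1L
      sizes[s] <- sizes[s] + 1L
    }
  }
  idx <- cumsum(sizes)
  train <- shuffled[seq_len(idx[1L])]
  validation <- shuffled[seq(idx[1L] + 1L, idx[2L])]
  test <- shuffled[seq(idx[2L] + 1L, idx[3L])]
  subgroups <- vapply(test, label_subgroup, character(1L),
                      train_set = train, combo_sep = combo_sep)
  structure(list(train = train, validation = validation, test = test,
                 subgroups = subgroups, seed = seed),
            class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("split_spec (seed %d): %d train / %d validation / %d test\n",
              x$seed, length(x$train), length(x$validation), length(x$test)))
  print(table(x$subgroups))
  invisible(x)
}

#' Subgroup tag for a test perturbation
#'
#' Tags a held-out perturbation by how much of it was seen during training:
#' combos become `combo_seen0/1/2` according to how many of their two
#' components are present as *single* perturbations in the train set; single
#' perturbations become `seen_single` when their gene occurs among the train
#' perturbations' components (alone or inside a combo), else `unseen_single`.
#'
#' @param test_perturbation One perturbation label.
#' @param train_set Character vector of training perturbation labels.
#' @param combo_sep Separator for combo labels.
#' @return One of `"combo_seen0"`, `"combo_seen1"`, `"combo_seen2"`,
#'   `"seen_single"`, `"unseen_single"`.
#' @export
label_subgroup <- function(test_perturbation, train_set, combo_sep = "+") {
  parts <- strsplit(test_perturbation, combo_sep, fixed = TRUE)[[1]]
  if (length(parts) > 2L) {
    stop("label '", test_perturbation, "' has more than 2 components")
  }
  train_parts <- strsplit(train_set, combo_sep, fixed = TRUE)
  if (length(parts) == 2L) {
    train_singles <- unlist(train_parts[lengths(train_parts) == 1L])
    paste0("combo_seen", sum(parts %in% train_singles))
  } else {
    if (parts %in% unlist(train_parts)) "seen_single" else "unseen_single"
  }
}
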