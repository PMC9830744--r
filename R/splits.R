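#' Deterministic sub-seed derivation
#'
#' Maps a master seed and a path of non-negative integer tags (e.g. repeat,
#' fold, bootstrap index) to a reproducible sub-seed, so that any single
#' bootstrap fit can be replayed in isolation. The derivation is a
#' splitmix-style integer hash folded into the 31-bit positive range.
#'
#' @param master Master integer seed.
#' @param ... Further integer tags identifying the stage.
#' @return A positive integer seed below 2^31.
#' @export
derive_seed <- function(master, ...) {
  tags <- c(as.numeric(master), vapply(list(...), as.numeric, 0))
  h <- 0
  for (t in tags) h <- (h * 1103515245 + t + 12345) %% 2147483647
  as.integer(h %% 2147483646) + 1L
}

#' Repeated, event-stratified K-fold splits
#'
#' Builds `k * repeats` train/test partitions. Within each repeat the folds
#' partition all rows; events and censored observations are allocated to
#' folds separately so that every fold carries its share of the (possibly
#' very rare) events. With fewer events than folds a warning is issued and
#' plain unstratified folds are used.
#'
#' @param m Number of samples.
#' @param events 0/1 event indicator of length `m`.
#' @param k Number of folds (>= 2).
#' @param repeats Number of independent repetitions.
#' @param seed Integer seed; identical seeds give identical splits.
#' @return A list of `fold_split` objects with fields `repeat_index`,
#'   `fold_index`, `train`, `test`.
#' @export
make_cv_splits <- function(m, events, k = 5L, repeats = 5L, seed = 1L) {
  stopifnot(k >= 2L, m >= k, length(events) == m)
  stratify <- sum(events == 1) >= k
  if (!stratify)
    warning("fewer events (", sum(events == 1), ") than folds (", k,
            "); using unstratified folds")
  splits <- list()
  for (rep_i in seq_len(repeats)) {
    fold_of <- integer(m)
    rs <- derive_seed(seed, 101L, rep_i)
    old <- .Random.seed_save()
    set.seed(rs)
    if (stratify) {
      for (grp in list(which(events == 1), which(events == 0))) {
        perm <- sample(grp)
        fold_of[perm] <- rep_len(seq_len(k), length(perm))
      }
    } else {
      fold_of[sample.int(m)] <- rep_len(seq_len(k), m)
    }
    .Random.seed_restore(old)
    for (fold_i in seq_len(k)) {
      test <- which(fold_of == fold_i)
      splits[[length(splits) + 1L]] <- structure(
        list(repeat_index = rep_i, fold_index = fold_i,
             train = setdiff(seq_len(m), test), test = test),
        class = "fold_split")
    }
  }
  splits
}

#' Bootstrap resample of a dataset
#'
#' Draws `m` rows with replacement and returns both the resampled dataset
#' and the drawn index multiset for audit.
#'
#' @param ds A [survival_dataset()].
#' @param seed Integer seed.
#' @return A list with `data` (the resampled `survival_dataset`) and
#'   `indices` (integer vector of length `m`).
#' @export
bootstrap_sample <- function(ds, seed) {
  m <- n_samples(ds)
  if (m < 2L) stop("cannot bootstrap a dataset with fewer than 2 rows")
  old <- .Random.seed_save()
  set.seed(seed)
  idx <- sample.int(m, m, replace = TRUE)
  .Random.seed_restore(old)
  list(data = subset_rows(ds, idx), indices = idx)
}

# Save/restore the global RNG state so that seeded internals do not
# perturb the caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

with_seed <- function(seed, code) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  code
}
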