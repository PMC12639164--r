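# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so library calls never perturb user RNG.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-stream seed from a master seed and one or two indices.
# Kept below 2^31 - 1 and independent of generation order so that records can
# be produced lesion-by-lesion or in bulk with identical results.
sub_seed <- function(master, i, j = 0L) {
  m <- as.double(master) %% 100003
  ((m * 20011 + as.double(i) * 7919 + as.double(j) * 104729) %% 2147483629) + 1
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_binary_labels <- function(labels) {
  if (anyNA(labels) || !all(labels %in% c(0, 1))) {
    stopf("labels must be 0/1 with no missing values")
  }
  if (all(labels == 1) || all(labels == 0)) {
    stopf("both classes must be present (got a single-class label vector)")
  }
  as.integer(labels)
}

check_scores <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stopf("scores and labels must have equal length")
  }
  if (anyNA(scores) || any(!is.finite(scores))) {
    stopf("scores must be finite and non-missing")
  }
  as.numeric(scores)
}
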