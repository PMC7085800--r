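# Independent reference implementations used as oracles. Deliberately naive
# and separate from the package code paths they check.

# Full three-operation edit-distance DP over tokens, plain double loop.
oracle_edit_distance <- function(a, b, sub_cost = 2) {
  m <- length(a)
  n <- length(b)
  d <- matrix(0L, m + 1, n + 1)
  d[, 1] <- 0:m
  d[1, ] <- 0:n
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      d[i + 1, j + 1] <- min(
        d[i, j + 1] + 1,
        d[i + 1, j] + 1,
        d[i, j] + if (a[i] == b[j]) 0 else sub_cost
      )
    }
  }
  d[m + 1, n + 1]
}

oracle_lev_ratio <- function(a, b, sub_cost = 2) {
  (length(a) + length(b) - oracle_edit_distance(a, b, sub_cost)) /
    (length(a) + length(b))
}

# Presence-count SIA: for each start sensor, fraction of its sequences in
# which each sensor occurs.
oracle_sia <- function(sequences) {
  starts <- vapply(sequences, `[`, character(1), 1)
  lapply(split(sequences, starts), function(sqs) {
    sensors <- sort(unique(unlist(sqs)))
    v <- vapply(sensors, function(s) {
      mean(vapply(sqs, function(sq) s %in% sq, logical(1)))
    }, numeric(1))
    v
  })
}

# Brute-force interval membership: for every event row, the set of activity
# instances (label + begin row) whose [begin, end] row span contains it.
# Spans are found by matching each begin marker to the next end marker of
# the same label.
oracle_spans <- function(events) {
  spans <- list()
  for (i in seq_len(nrow(events))) {
    if (!is.na(events$marker[i]) && events$marker[i] == "begin") {
      lab <- events$activity[i]
      ends <- which(events$marker == "end" & events$activity == lab)
      e <- ends[ends >= i][1]
      if (!is.na(e)) {
        spans[[length(spans) + 1]] <- list(label = lab, from = i, to = e)
      }
    }
  }
  spans
}

# Random token sequences over a small alphabet.
random_seq <- function(max_len = 12, alphabet = sprintf("M%03d", 1:8)) {
  sample(alphabet, sample.int(max_len, 1), replace = TRUE)
}

# Joint de-noising rule applied the slow explicit way: importance filter
# first, then consecutive-duplicate removal.
oracle_denoise <- function(sq, imp_row, w) {
  keep <- vapply(sq, function(s) {
    v <- if (s %in% names(imp_row)) imp_row[[s]] else 0
    v > w
  }, logical(1))
  out <- sq[keep]
  if (length(out) > 1) {
    out <- out[c(TRUE, out[-1] != out[-length(out)])]
  }
  if (length(out) == 0) out <- sq[1]
  out
}
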