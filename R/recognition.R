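#' Recognition configuration
#'
#' Bundles the weights and vote count of the similarity-voting classifier
#' and the parameters of the stages that feed it.
#'
#' @param w1 Weight of each of the two time terms (begin hour, end hour).
#' @param w2 Weight of the sequence-similarity term. The weights must
#'   satisfy `2*w1 + w2 = 1` (so similarity is bounded by 1) and
#'   `2*w1 <= w2` (the sequence carries at least half the weight). Defaults
#'   `w1 = 0.15`, `w2 = 0.7`.
#' @param n Number of most-similar training instances that vote (default 5).
#'   Should be smaller than the number of activity classes.
#' @param w_threshold De-noising importance threshold passed to
#'   [denoise_sequence()] (default 0.25).
#' @param k Number of time clusters: `"auto"` (elbow method via
#'   [select_k()]) or a positive integer.
#' @param dedup Duplicate-removal mode for de-noising, `"consecutive"` or
#'   `"global"`.
#' @param sub_cost Substitution cost of the token edit distance; 2 (default)
#'   keeps the Levenshtein ratio in `[0, 1]`, 1 gives the plain unit-cost
#'   distance for sensitivity analysis.
#' @return A list of class `recognition_config`.
#' @export
recognition_config <- function(w1 = 0.15, w2 = 0.7, n = 5L,
                               w_threshold = 0.25, k = "auto",
                               dedup = c("consecutive", "global"),
                               sub_cost = 2) {
  dedup <- match.arg(dedup)
  if (abs(2 * w1 + w2 - 1) > 1e-9) {
    stop("weights must satisfy 2*w1 + w2 = 1 (got 2*", w1, " + ", w2, ")",
         call. = FALSE)
  }
  if (2 * w1 > w2 + 1e-9) {
    stop("weights must satisfy 2*w1 <= w2", call. = FALSE)
  }
  if (n < 1) stop("n must be a positive integer", call. = FALSE)
  if (!identical(k, "auto") && (!is.numeric(k) || k < 1)) {
    stop("k must be \"auto\" or a positive integer", call. = FALSE)
  }
  structure(list(w1 = w1, w2 = w2, n = as.integer(n),
                 w_threshold = w_threshold, k = k, dedup = dedup,
                 sub_cost = sub_cost),
            class = "recognition_config")
}

#' Levenshtein ratio between two sensor sequences
#'
#' Normalised token-level edit-distance similarity
#' `(|sq1| + |sq2| - ldist) / (|sq1| + |sq2|)`, where `ldist` is the edit
#' distance with insertions and deletions costing 1 and substitutions
#' costing `sub_cost` (2 by default, which bounds the ratio in `[0, 1]` and
#' makes it the classic sequence-matching ratio). Sequences are compared as
#' whole sensor-id tokens, never as concatenated characters, so `"M004"`
#' and `"M005"` are simply unequal.
#'
#' @param sq1,sq2 Non-empty character vectors of sensor ids.
#' @param sub_cost Substitution cost (default 2).
#' @return Similarity in `[0, 1]` (for `sub_cost = 2`).
#' @export
#' @examples
#' levenshtein_ratio(c("A", "B", "C"), c("A", "B", "C"))  # 1
#' levenshtein_ratio(c("A", "B"), c("C", "D"))            # 0
levenshtein_ratio <- function(sq1, sq2, sub_cost = 2) {
  if (length(sq1) == 0 || length(sq2) == 0) {
    stop("sensor sequences must be non-empty", call. = FALSE)
  }
  codes <- match(c(sq1, sq2), unique(c(sq1, sq2)))
  a <- codes[seq_along(sq1)]
  b <- codes[length(sq1) + seq_along(sq2)]
  total <- length(sq1) + length(sq2)
  (total - .token_edit_distance(a, b, as.integer(sub_cost))) / total
}

#' Hybrid time/sequence similarity between two activity instances
#'
#' `w1*(24 - |a.bt - t.bt|)/24 + w1*(24 - |a.et - t.et|)/24 +
#'  w2*levenshtein_ratio(a.sq, t.sq)`: the two hour gaps are linear (not
#' circular) absolute differences normalised by the 24-hour day. Under the
#' constraint `2*w1 + w2 = 1` the similarity lies in `[0, 1]` and equals 1
#' exactly for identical instances. Symmetric in its two arguments.
#'
#' @param a,t Activity instances: lists or one-row tibbles with `bt`, `et`
#'   and `sq` (both de-noised with the same SIA and threshold).
#' @param cfg A [recognition_config()].
#' @return Similarity score.
#' @export
similarity <- function(a, t, cfg = recognition_config()) {
  sq_a <- if (is.list(a$sq) && !is.character(a$sq)) a$sq[[1]] else a$sq
  sq_t <- if (is.list(t$sq) && !is.character(t$sq)) t$sq[[1]] else t$sq
  cfg$w1 * (24 - abs(a$bt - t$bt)) / 24 +
    cfg$w1 * (24 - abs(a$et - t$et)) / 24 +
    cfg$w2 * levenshtein_ratio(sq_a, sq_t, cfg$sub_cost)
}

#' Recognise one activity instance by similarity voting
#'
#' Assigns the query to its nearest time cluster, ranks the training
#' instances of that cluster by [similarity()] (descending) and returns the
#' majority label among the top `cfg$n`. Label ties are broken by the
#' greater summed similarity, then lexicographically, so the prediction is
#' fully deterministic.
#'
#' @param train A `casas_activities` tibble of de-noised training instances.
#' @param model A `cluster_model` fitted on `time_points(train)`, so
#'   `model$assignment` maps training rows to clusters.
#' @param t Query instance (list or one-row tibble with `bt`, `et`, `sq`),
#'   de-noised with the same SIA.
#' @param cfg A [recognition_config()].
#' @return List with `label` (the prediction), `cluster`, and `neighbours`,
#'   a tibble of the voting instances (`label`, `ratio`).
#' @details An empty cluster falls back to ranking over all training
#'   instances, with a warning; a cluster smaller than `n` votes with all
#'   its members.
#' @export
recognize <- function(train, model, t, cfg = recognition_config()) {
  cl <- predict_cluster(model, c(t$bt, t$et))
  members <- which(model$assignment == cl)
  if (length(members) == 0) {
    warning("no training instances in cluster ", cl,
            "; ranking over the full training set", call. = FALSE)
    members <- seq_len(nrow(train))
  }
  ratios <- vapply(members, function(i) {
    similarity(train[i, ], t, cfg)
  }, numeric(1))
  ord <- order(-ratios)
  top <- ord[seq_len(min(cfg$n, length(ord)))]
  top_labels <- train$label[members[top]]
  top_ratios <- ratios[top]
  votes <- tapply(rep(1L, length(top_labels)), top_labels, sum)
  sums <- tapply(top_ratios, top_labels, sum)
  cand <- names(votes)[votes == max(votes)]
  if (length(cand) > 1) {
    cand <- cand[sums[cand] == max(sums[cand])]
  }
  list(label = sort(cand)[1],
       cluster = cl,
       neighbours = tibble::tibble(label = top_labels, ratio = top_ratios))
}
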