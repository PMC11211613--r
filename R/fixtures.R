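# Episode/sequence fixtures. An episode is a set of feature indices in
# 1..n_features (one feature = one unit per layer); a sequence is an ordered
# list of episodes. The two canonical sets are three sequences of five
# episodes each: one fully orthogonal, one with a controlled sharing pattern
# (a feature shared by two episodes appears in both).

.new_seqset <- function(sequences, n_features = 75) {
  episodes <- do.call(c, sequences)
  stopifnot(length(episodes) >= 1)
  for (ep in episodes) {
    if (length(ep) == 0) stop("episode with no features")
    if (any(ep < 1 | ep > n_features))
      stop("feature index out of range 1..", n_features)
  }
  ids <- seq_along(episodes)
  sharing <- list()
  for (a in ids) for (b in ids) {
    if (b <= a) next
    sh <- intersect(episodes[[a]], episodes[[b]])
    if (length(sh))
      sharing[[length(sharing) + 1L]] <-
        list(a = a, b = b, features = sort(sh))
  }
  structure(list(sequences = sequences, episodes = episodes,
                 n_features = n_features, sharing_map = sharing),
            class = "tg_seqset")
}

#' @export
print.tg_seqset <- function(x, ...) {
  cat("tg_seqset:", length(x$sequences), "sequences,",
      length(x$episodes), "episodes,",
      length(unique(unlist(x$episodes))), "distinct features,",
      length(x$sharing_map), "shared pairs\n")
  invisible(x)
}

#' Canonical orthogonal sequence set
#'
#' Three sequences of five episodes each; the 15 episodes are pairwise
#' disjoint and together use all 75 features. Episode sizes vary between 4
#' and 6 features; episode 7 (second of sequence 2) is features 30-35 and
#' episode 6 is features 26-29.
#'
#' @return A `tg_seqset`.
#' @export
make_orthogonal_set <- function() {
  s1 <- list(1:5, 6:10, 11:15, 16:20, 21:25)
  s2 <- list(26:29, 30:35, 36:40, 41:45, 46:50)
  s3 <- list(51:55, 56:60, 61:65, 66:71, 72:75)
  .new_seqset(list(s1, s2, s3))
}

#' Canonical non-orthogonal sequence set (shared features)
#'
#' Same three-sequence, five-episode skeleton with a fixed sharing pattern:
#' episode 2 shares two features (70, 71) with episode 14; episode 3 shares
#' one feature with episode 7 (30) and one with episode 12 (56); and one
#' episode of the second sequence shares feature 44 with episode 13. The
#' fraction of shared features per affected episode lies in 20-35%.
#'
#' @param variant Which episode of the second sequence shares feature 44 with
#'   episode 13: `"ep9"` (the default, fourth episode of sequence 2) or
#'   `"ep14_text"`, an alternative reading in which episode 9 shares with
#'   episode 14 instead. The two variants describe the same total amount of
#'   sharing; `"ep9"` is the canonical fixture.
#' @return A `tg_seqset`.
#' @export
make_nonorthogonal_set <- function(variant = c("ep9", "ep14_text")) {
  variant <- match.arg(variant)
  s1 <- list(c(1, 2, 3, 4),                 # Ep1
             c(7, 8, 9, 10, 70, 71),        # Ep2: 70,71 shared with Ep14
             c(11, 12, 13, 14, 30, 56),     # Ep3: 30 w/ Ep7, 56 w/ Ep12
             15:19,                         # Ep4
             20:24)                         # Ep5
  s2 <- list(25:29,                         # Ep6
             30:34,                         # Ep7: 30 shared with Ep3
             35:39,                         # Ep8
             c(40, 41, 42, 43, 44),         # Ep9: 44 shared with Ep13
             45:49)                         # Ep10
  s3 <- list(50:54,                         # Ep11
             55:59,                         # Ep12: 56 shared with Ep3
             c(44, 61, 62, 64, 65),         # Ep13
             c(66, 67, 68, 69, 70, 71),     # Ep14
             72:75)                         # Ep15
  if (variant == "ep14_text") {
    # episode 9 shares with episode 14 instead of 13
    s2[[4]] <- c(40, 41, 42, 43, 66)
    s3[[3]] <- c(60, 61, 62, 64, 65)
  }
  .new_seqset(list(s1, s2, s3))
}

#' Random sequence set with controlled sharing
#'
#' Builds a reproducible set of sequences of episodes with optional pairwise
#' feature sharing, for property testing.
#'
#' @param n_sequences Number of sequences.
#' @param episodes_per_seq Episodes per sequence.
#' @param size_range Length-2 integer range of episode sizes.
#' @param sharing_spec List of `list(a =, b =, n =)` entries requesting `n`
#'   shared features between global episode ids `a` and `b`.
#' @param seed RNG seed.
#' @param n_features Layer size (number of available features).
#' @return A `tg_seqset`.
#' @export
make_random_set <- function(n_sequences = 3, episodes_per_seq = 5,
                            size_range = c(4, 6), sharing_spec = list(),
                            seed = 1, n_features = 75) {
  set.seed(seed)
  n_ep <- n_sequences * episodes_per_seq
  sizes <- sample(seq(size_range[1], size_range[2]), n_ep, replace = TRUE)
  n_shared <- sum(vapply(sharing_spec, function(s) s$n, numeric(1)))
  if (sum(sizes) - n_shared > n_features)
    stop("infeasible sharing_spec: needs more features than available")
  pool <- sample(n_features)
  eps <- vector("list", n_ep)
  ptr <- 1
  for (i in seq_len(n_ep)) {
    eps[[i]] <- sort(pool[ptr:(ptr + sizes[i] - 1)])
    ptr <- ptr + sizes[i]
  }
  for (s in sharing_spec) {
    stopifnot(s$a >= 1, s$b <= n_ep, s$n >= 1)
    give <- eps[[s$a]][seq_len(s$n)]
    keep <- eps[[s$b]][seq_len(length(eps[[s$b]]) - s$n)]
    eps[[s$b]] <- sort(c(keep, give))
  }
  seqs <- split(eps, rep(seq_len(n_sequences), each = episodes_per_seq))
  names(seqs) <- NULL
  .new_seqset(lapply(seqs, identity), n_features)
}

#' Rectangular input schedule for named units and populations
#'
#' Builds the event table consumed by the simulator: a rectangular drive of
#' given amplitude to the pyramidal (`"p"`) and/or fast-interneuron (`"f"`)
#' populations of the given features in the given layer.
#'
#' @param features Integer feature indices (1-based).
#' @param layer One of `"WM"`, `"L1"`, `"L2"`.
#' @param start,end Window (s).
#' @param amplitude Drive amplitude (spikes/s-equivalent).
#' @param targets Character subset of `c("p", "f")`.
#' @return A data.frame with columns `feature`, `layer`, `pop`, `start`,
#'   `end`, `amp`.
#' @export
make_inputs <- function(features, layer = "WM", start, end, amplitude,
                        targets = "p") {
  stopifnot(length(targets) >= 1, all(targets %in% c("p", "f")),
            end > start, length(features) >= 1)
  expand.grid(feature = features, layer = layer, pop = targets,
              start = start, end = end, amp = amplitude,
              stringsAsFactors = FALSE)
}

#' Write / read a sequence set as structured text
#'
#' Serializes a `tg_seqset` to a YAML file (a list of sequences, each a list
#' of sorted feature vectors) and reads it back.
#'
#' @param x A `tg_seqset`.
#' @param path File path.
#' @return `read_sequence_set` returns a `tg_seqset`;
#'   `write_sequence_set` returns `path` invisibly.
#' @export
write_sequence_set <- function(x, path) {
  stopifnot(inherits(x, "tg_seqset"))
  obj <- list(n_features = x$n_features,
              sequences = lapply(x$sequences,
                                 function(s) lapply(s, function(e) sort(as.integer(e)))))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_sequence_set
#' @export
read_sequence_set <- function(path) {
  obj <- yaml::read_yaml(path)
  seqs <- lapply(obj$sequences, function(s) lapply(s, as.integer))
  .new_seqset(seqs, n_features = obj$n_features)
}
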