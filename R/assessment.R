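# Cycle-by-cycle scoring of sequence replay. The theta generator's own trace
# is the clock: cycles are delimited by upward crossings through 30% of its
# range, and the on-phase is the supra-threshold segment. An episode counts
# as recovered within a cycle if all of its features' L2 pyramidal spike
# densities exceed the detection threshold simultaneously for at least one
# integration step; an episode is correctly placed if its first crossing is
# later than that of every detected earlier episode.

#' Segment a theta-generator trace into cycles
#'
#' Cycles are delimited by upward crossings of the trace through a fixed
#' fraction of its (max - min) range. The delimiter fraction (default 0.3)
#' is placed below the half-range point so that replay triggered on the
#' rising flank of the theta wave falls inside the cycle it belongs to; the
#' on-phase is the supra-threshold segment above the same fraction.
#'
#' @param theta_trace Spike-density trace of the theta generator (burn-in
#'   removed by the caller).
#' @param dt Sampling interval (s).
#' @param frac Crossing threshold as a fraction of the trace range.
#' @return A data.frame of class `tg_cycles` with columns `cycle`, `start`,
#'   `end`, `on_start`, `on_end` (all in s relative to the trace start) and
#'   `complete` (on-phase fully inside the trace). For an (effectively)
#'   constant trace, a single unbounded on-phase is returned with attribute
#'   `constant = TRUE`.
#' @export
theta_cycles <- function(theta_trace, dt, frac = 0.3) {
  n <- length(theta_trace)
  rng <- range(theta_trace)
  if (diff(rng) < 0.1) {
    out <- data.frame(cycle = 1L, start = 0, end = (n - 1) * dt,
                      on_start = 0, on_end = (n - 1) * dt, complete = FALSE)
    class(out) <- c("tg_cycles", "data.frame")
    attr(out, "constant") <- TRUE
    return(out)
  }
  th <- rng[1] + frac * diff(rng)
  above <- theta_trace > th
  up <- which(!above[-n] & above[-1]) + 1L   # first index above threshold
  if (length(up) < 1) {
    out <- data.frame(cycle = integer(0), start = numeric(0),
                      end = numeric(0), on_start = numeric(0),
                      on_end = numeric(0), complete = logical(0))
    class(out) <- c("tg_cycles", "data.frame")
    attr(out, "constant") <- FALSE
    return(out)
  }
  starts <- up
  ends <- c(up[-1], n + 1L)
  rows <- lapply(seq_along(starts), function(i) {
    seg <- starts[i]:(ends[i] - 1L)
    off <- seg[which(!above[seg])[1]]
    complete <- !is.na(off)
    data.frame(cycle = i, start = (starts[i] - 1L) * dt,
               end = (ends[i] - 2L) * dt,
               on_start = (starts[i] - 1L) * dt,
               on_end = if (complete) (off - 2L) * dt else (ends[i] - 2L) * dt,
               complete = complete)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("tg_cycles", "data.frame")
  attr(out, "constant") <- FALSE
  out
}

.cycle_span <- function(cycle, dt, n_max) {
  i0 <- round(cycle$start / dt) + 1L
  i1 <- min(round(cycle$end / dt) + 1L, n_max)
  i0:i1
}

#' Episode recovery within one theta cycle
#'
#' `TRUE` iff there exists an integration step inside the cycle at which all
#' features of the episode have spike density above the threshold
#' simultaneously.
#'
#' @param L2_trace Matrix (features x time) of L2 pyramidal spike densities.
#' @param episode Integer feature indices of the episode.
#' @param cycle One row of [theta_cycles()] output.
#' @param dt Sampling interval (s).
#' @param threshold Detection threshold (default 3.5 = 70% of the 5 spikes/s
#'   ceiling).
#' @return Logical, with attribute `first_crossing` (s, `NA` if not
#'   detected): the first step of the simultaneous conjunction.
#' @export
detect_episode <- function(L2_trace, episode, cycle, dt, threshold = 3.5) {
  if (any(episode < 1 | episode > nrow(L2_trace)))
    stop("episode references features absent from the layer")
  span <- .cycle_span(cycle, dt, ncol(L2_trace))
  seg <- L2_trace[episode, span, drop = FALSE]
  all_above <- colSums(seg > threshold) == length(episode)
  hit <- which(all_above)[1]
  if (is.na(hit)) return(structure(FALSE, first_crossing = NA_real_))
  structure(TRUE, first_crossing = (span[hit] - 1L) * dt)
}

#' Ordered-sequence recovery within one theta cycle
#'
#' Scores each episode of a sequence by [detect_episode()] and marks the
#' in-order recoveries: episode m counts as correctly placed iff it is
#' detected and its first simultaneous-crossing time is strictly later than
#' that of every *detected* earlier episode (ties count as an ordering
#' failure). Episodes that were not detected at all do not penalize the
#' placement of later ones, so a missed first episode leaves the rest of the
#' sequence scorable.
#'
#' @inheritParams detect_episode
#' @param sequence List of episodes (integer feature vectors) in temporal
#'   order.
#' @return `list(episode = logical vector (in-order prefix),
#'   detected = logical vector (raw detection),
#'   first_crossing = numeric vector, sequence = all episodes in order)`.
#' @export
detect_sequence <- function(L2_trace, sequence, cycle, dt, threshold = 3.5) {
  det <- lapply(sequence, detect_episode, L2_trace = L2_trace, cycle = cycle,
                dt = dt, threshold = threshold)
  detected <- vapply(det, as.logical, logical(1))
  fc <- vapply(det, attr, numeric(1), "first_crossing")
  ok <- logical(length(sequence))
  last <- -Inf
  for (m in seq_along(sequence)) {
    if (detected[m] && fc[m] > last) {
      ok[m] <- TRUE
      last <- fc[m]
    }
  }
  list(episode = ok, detected = detected, first_crossing = fc,
       sequence = all(ok))
}

#' Success table of the retrieval assessment
#'
#' Reproduces the cycle-by-cycle assessment: for each sequence, `n_runs`
#' retrieval simulations of `duration` seconds with distinct noise seeds, one
#' cue (a feature of the sequence's first episode) per run; every theta cycle
#' whose on-phase falls inside the scored window is evaluated with
#' [detect_sequence()], and results are expressed as the percentage of
#' evaluated cycles in which each episode position was correctly recovered,
#' with an unweighted mean row across sequences.
#'
#' @param trained_network A trained `tg_network` in retrieval mode.
#' @param sequence_set A `tg_seqset` (defaults to the set the network was
#'   trained on).
#' @param n_runs Simulations per sequence.
#' @param duration Scored window per run (s).
#' @param seed Master seed; per-(sequence, run) seeds are derived from it.
#' @param cue_feature_fn Function mapping a sequence (list of episodes) to
#'   the cue feature; default: first feature of the first episode.
#' @param threshold Detection threshold.
#' @return A `tg_success_table`: matrix (sequences + Mean) x episode
#'   positions, with metadata attributes (`n_runs`, `cycles_per_run`,
#'   `duration`, `seed`).
#' @export
success_table <- function(trained_network, sequence_set = NULL, n_runs = 10,
                          duration = 1.0, seed = 1,
                          cue_feature_fn = function(s) s[[1]][1],
                          threshold = 3.5) {
  stopifnot(n_runs >= 1)
  net <- trained_network
  seqset <- sequence_set %||% net$sequences
  stopifnot(inherits(seqset, "tg_seqset"))
  n_seq <- length(seqset$sequences)
  n_pos <- max(lengths(seqset$sequences))
  counts <- matrix(0, n_seq, n_pos)
  evaluated <- numeric(n_seq)
  cycles_per_run <- NA
  for (s in seq_len(n_seq)) {
    sq <- seqset$sequences[[s]]
    cue <- cue_feature_fn(sq)
    for (r in seq_len(n_runs)) {
      run_seed <- (seed * 10007L + s * 101L + r) %% .Machine$integer.max
      sim <- run_retrieval(net, cues = data.frame(feature = cue, onset = 0),
                           duration = duration, seed = run_seed)
      sc <- score_retrieval(sim, sq, duration = duration,
                            threshold = threshold)
      counts[s, seq_along(sq)] <- counts[s, seq_along(sq)] + sc$counts
      evaluated[s] <- evaluated[s] + sc$n_cycles
      cycles_per_run <- sc$n_cycles
    }
  }
  pct <- 100 * counts / evaluated
  tab <- rbind(pct, Mean = colMeans(pct))
  rownames(tab) <- c(paste("Sequence", seq_len(n_seq)), "Mean")
  colnames(tab) <- paste("Episode", seq_len(n_pos))
  structure(tab, class = c("tg_success_table", "matrix"),
            n_runs = n_runs, cycles_per_run = cycles_per_run,
            duration = duration, seed = seed)
}

#' Score one retrieval simulation cycle by cycle
#'
#' Segments the theta trace of a retrieval run, selects the scored window
#' (the first `round(duration * f_theta)` full cycles starting at the first
#' upward crossing after cue onset), and applies [detect_sequence()] to each.
#'
#' @param sim A `tg_sim` from [run_retrieval()].
#' @param sequence List of episodes in order.
#' @param duration Scored window length (s).
#' @param threshold Detection threshold.
#' @return `list(counts = per-episode success counts, n_cycles =, per_cycle =
#'   list of detect_sequence results, cycles = the scored cycle table)`.
#' @export
score_retrieval <- function(sim, sequence, duration = 1.0, threshold = 3.5) {
  theta <- layer_trace(sim, "theta")
  L2 <- layer_trace(sim, "L2")
  cyc <- theta_cycles(theta, sim$dt)
  t_cue <- attr(sim, "cue_onset") %||% 0
  cyc <- cyc[cyc$start >= t_cue & cyc$complete, , drop = FALSE]
  if (nrow(cyc) == 0)
    return(list(counts = numeric(length(sequence)), n_cycles = 0,
                per_cycle = list(), cycles = cyc))
  period <- if (nrow(cyc) > 1) stats::median(diff(cyc$start)) else
    cyc$end[1] - cyc$start[1]
  n_cycles <- max(1L, round(duration / period))
  cyc <- head(cyc, n_cycles)
  per_cycle <- lapply(seq_len(nrow(cyc)), function(i)
    detect_sequence(L2, sequence, cyc[i, ], sim$dt, threshold))
  counts <- Reduce(`+`, lapply(per_cycle, function(x) as.numeric(x$episode)))
  list(counts = counts, n_cycles = nrow(cyc), per_cycle = per_cycle,
       cycles = cyc)
}

#' @export
print.tg_success_table <- function(x, ...) {
  cat("Percentage of theta cycles with correct recovery",
      sprintf("(%d runs, %s cycles/run)\n", attr(x, "n_runs"),
              format(attr(x, "cycles_per_run"))))
  print(round(unclass(x), 2))
  invisible(x)
}

#' Export a success table as columnar text and JSON
#'
#' @param x A `tg_success_table`.
#' @param path Output path without extension; writes `<path>.txt` and, if
#'   jsonlite is installed, `<path>.json`.
#' @return Invisibly, the paths written.
#' @export
write_success_table <- function(x, path) {
  txt <- paste0(path, ".txt")
  hdr <- sprintf("# n_runs=%d cycles_per_run=%s duration=%s seed=%s",
                 attr(x, "n_runs"), format(attr(x, "cycles_per_run")),
                 format(attr(x, "duration")), format(attr(x, "seed")))
  con <- file(txt, "w")
  writeLines(hdr, con)
  write.table(round(unclass(x), 3), con, sep = "\t", quote = FALSE,
              col.names = NA)
  close(con)
  paths <- txt
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    js <- paste0(path, ".json")
    jsonlite::write_json(list(table = as.data.frame(unclass(x)),
                              n_runs = attr(x, "n_runs"),
                              cycles_per_run = attr(x, "cycles_per_run")),
                         js, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, js)
  }
  invisible(paths)
}

#' Count superimposed-episode steps within a cycle
#'
#' Number of integration steps inside the cycle at which two or more
#' distinct episodes satisfy the full-episode detection conjunction
#' simultaneously, excluding pairs whose co-activation is explained by a
#' shared feature alone (pairs that share at least one feature).
#'
#' @inheritParams detect_episode
#' @param sequence_set A `tg_seqset`; all stored episodes are considered.
#' @return Integer count of superposition steps.
#' @export
superposition_score <- function(L2_trace, sequence_set, cycle, dt,
                                threshold = 3.5) {
  eps <- sequence_set$episodes
  span <- .cycle_span(cycle, dt, ncol(L2_trace))
  above <- L2_trace[, span, drop = FALSE] > threshold
  act <- vapply(eps, function(e)
    colSums(above[e, , drop = FALSE]) == length(e),
    logical(length(span)))
  if (is.null(dim(act))) act <- matrix(act, nrow = 1)
  shares <- function(a, b) length(intersect(eps[[a]], eps[[b]])) > 0
  count <- 0L
  for (t in seq_len(nrow(act))) {
    on <- which(act[t, ])
    if (length(on) < 2) next
    pairs <- combn(on, 2)
    indep <- any(!apply(pairs, 2, function(pr) shares(pr[1], pr[2])))
    if (indep) count <- count + 1L
  }
  count
}

#' Detect hybrid (recombined) sequences within theta cycles
#'
#' A cycle contains a hybrid when an ordered run of two or more
#' consecutive-position episodes of one stored sequence is followed, later in
#' the same cycle, by an ordered run of episodes of a different sequence, and
#' the two runs are joined through a shared feature: some episode of the
#' first run shares a feature with the suffix's starting episode or with its
#' within-sequence predecessor. On a fully orthogonal set no cycle can
#' qualify.
#'
#' @param sim A `tg_sim` (e.g. from [run_isolation()]).
#' @param sequence_set The trained `tg_seqset`.
#' @param burn_in Seconds discarded before cycle segmentation.
#' @param threshold Detection threshold (spikes/s).
#' @return A data.frame with one row per hybrid found: `cycle`, `seq_a`,
#'   `prefix_len`, `seq_b`, `suffix_start`.
#' @export
detect_hybrids <- function(sim, sequence_set, burn_in = 0.5, threshold = 3.5) {
  th <- layer_trace(sim, "theta")
  L2 <- layer_trace(sim, "L2")
  cyc <- theta_cycles(th, sim$dt)
  cyc <- cyc[cyc$start >= burn_in & cyc$complete, , drop = FALSE]
  seqs <- sequence_set$sequences
  out <- NULL
  shares <- function(e1, e2) length(intersect(e1, e2)) > 0
  for (i in seq_len(nrow(cyc))) {
    det <- lapply(seqs, detect_sequence, L2_trace = L2, cycle = cyc[i, ],
                  dt = sim$dt, threshold = threshold)
    for (a in seq_along(seqs)) {
      da <- det[[a]]
      # ordered runs of >= 2 consecutive positions in sequence a
      runs_a <- .ordered_runs(da, min_len = 2)
      if (!length(runs_a)) next
      for (b in seq_along(seqs)) {
        if (b == a) next
        db <- det[[b]]
        runs_b <- .ordered_runs(db, min_len = 1)
        for (ra in runs_a) for (rb in runs_b) {
          t_a_end <- da$first_crossing[ra[length(ra)]]
          t_b_start <- db$first_crossing[rb[1]]
          if (!(t_b_start > t_a_end)) next
          junction <- vapply(ra, function(p) {
            e_a <- seqs[[a]][[p]]
            hit <- shares(e_a, seqs[[b]][[rb[1]]])
            if (!hit && rb[1] > 1)
              hit <- shares(e_a, seqs[[b]][[rb[1] - 1]])
            hit
          }, logical(1))
          if (any(junction)) {
            out <- rbind(out, data.frame(cycle = i, seq_a = a,
                                         prefix_len = length(ra),
                                         seq_b = b, suffix_start = rb[1]))
          }
        }
      }
    }
  }
  out %||% data.frame(cycle = integer(0), seq_a = integer(0),
                      prefix_len = integer(0), seq_b = integer(0),
                      suffix_start = integer(0))
}

# maximal runs of consecutive positions detected in increasing temporal
# order within a cycle
.ordered_runs <- function(det, min_len = 2) {
  ok <- which(det$detected)
  runs <- list()
  cur <- integer(0)
  for (p in ok) {
    if (length(cur) && p == cur[length(cur)] + 1L &&
        det$first_crossing[p] > det$first_crossing[cur[length(cur)]]) {
      cur <- c(cur, p)
    } else {
      if (length(cur) >= min_len) runs[[length(runs) + 1L]] <- cur
      cur <- p
    }
  }
  if (length(cur) >= min_len) runs[[length(runs) + 1L]] <- cur
  runs
}
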