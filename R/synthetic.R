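#' Generate an i.i.d. background sequence set
#'
#' Letters are drawn independently from the given composition; output is
#' byte-identical for a given seed.
#'
#' @param n_seq Number of sequences (>= 1).
#' @param L Sequence length in bp (>= 1).
#' @param bg 4 letter frequencies (A, C, G, T); default uniform.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param role Role of the resulting set.
#' @param prefix Record id prefix.
#' @return An `mz_seqset` tibble.
#' @export
generate_background_set <- function(n_seq, L, bg = rep(0.25, 4), seed = 1L,
                                    role = c("primary", "control"),
                                    prefix = "seq") {
  role <- arg_match(role)
  stopifnot(n_seq >= 1, L >= 1)
  check_background(bg)
  gen <- function() {
    letters <- sample(DNA_LETTERS, n_seq * L, replace = TRUE, prob = bg)
    apply(matrix(letters, nrow = n_seq), 1L, paste, collapse = "")
  }
  seqs <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  sequence_set(sprintf("%s_%04d", prefix, seq_len(n_seq)), seqs, role = role)
}

sample_site <- function(m, consensus_only = FALSE) {
  if (consensus_only) return(consensus(m))
  paste(apply(m$probs, 1L, function(p) sample(colnames(m$probs), 1L, prob = p)),
        collapse = "")
}

#' Plant motif sites into a sequence set
#'
#' Each sequence independently receives one site with probability `occupancy`.
#' Site letters are sampled from the motif's probability matrix (or its
#' consensus with `consensus_only = TRUE`) so planted-score distributions are
#' realistic. Placement of the site's center relative to the sequence center
#' is `"uniform"` over valid starts, `"gaussian"` with mean `mu` and sd
#' `sigma` bp (out-of-range draws are resampled rather than clamped, to avoid
#' artifactual edge pile-ups), or `"fixed"` at start `offset`. With strand
#' policy `"both"`, planted sites go on either strand with equal probability
#' (the reverse complement is inserted for `"-"`).
#'
#' @param seqs An `mz_seqset` (data-frame-first).
#' @param motif The `mz_motif` to plant.
#' @param occupancy Per-sequence planting probability in \[0, 1\].
#' @param placement `"gaussian"` (default), `"uniform"` or `"fixed"`.
#' @param mu,sigma Gaussian center offset (bp, relative to the sequence
#'   center) and sd (bp, > 0). Defaults 0 and 30.
#' @param offset 0-based start for `"fixed"` placement.
#' @param strands `"both"` (default) or `"forward"`.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param consensus_only Plant the consensus string instead of sampled sites.
#' @return The modified `mz_seqset`, with a `truth` attribute tibble
#'   (`seq_id`, `planted`, `start`, `strand`) retrievable via
#'   [planted_truth()].
#' @export
plant_motifs <- function(seqs, motif, occupancy, placement = c("gaussian", "uniform", "fixed"),
                         mu = 0, sigma = 30, offset = NULL,
                         strands = c("both", "forward"), seed = 1L,
                         consensus_only = FALSE) {
  placement <- arg_match(placement)
  strands <- arg_match(strands)
  stopifnot(inherits(motif, "mz_motif"), occupancy >= 0, occupancy <= 1)
  L <- seqset_L(seqs)
  w <- motif_width(motif)
  if (L < w) abort("sequences are shorter than the motif")
  if (placement == "gaussian" && sigma <= 0) abort("'sigma' must be positive")
  if (placement == "fixed") {
    if (is.null(offset) || offset < 0 || offset > L - w) {
      abort(paste0("fixed 'offset' must lie in [0, ", L - w, "]"))
    }
  }
  center_L <- (L - 1) / 2
  draw_start <- function() {
    switch(placement,
      uniform = sample.int(L - w + 1L, 1L) - 1L,
      fixed = as.integer(offset),
      gaussian = {
        repeat {
          st <- round(center_L + rnorm(1L, mu, sigma) - (w - 1) / 2)
          if (st >= 0 && st <= L - w) return(as.integer(st))
        }
      })
  }
  run <- function() {
    n <- nrow(seqs)
    planted <- runif(n) < occupancy
    starts <- rep(NA_integer_, n)
    strand <- rep(NA_character_, n)
    out <- seqs$seq
    for (i in which(planted)) {
      st <- draw_start()
      sd_ <- if (strands == "both") sample(c("+", "-"), 1L) else "+"
      site <- sample_site(motif, consensus_only)
      if (sd_ == "-") site <- revcomp_chr(site)
      substr(out[i], st + 1L, st + w) <- site
      starts[i] <- st
      strand[i] <- sd_
    }
    list(seq = out,
         truth = tibble(seq_id = seqs$id, planted = planted, start = starts,
                        strand = strand))
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  out <- seqs
  out$seq <- res$seq
  attr(out, "truth") <- res$truth
  out
}

#' Planted-site truth table of a synthetic sequence set
#' @param seqs An `mz_seqset` produced by [plant_motifs()].
#' @return The truth tibble (`seq_id`, `planted`, `start`, `strand`).
#' @export
planted_truth <- function(seqs) {
  attr(seqs, "truth", exact = TRUE) %||%
    abort("no planted-site truth attached to this sequence set")
}

#' Built-in synthetic demonstration motif
#'
#' A sharp, synthetic AP-1-like 8-position DNA motif (consensus `TGACTCAG`)
#' used by the paired fixtures and examples. It is constructed here, not taken
#' from any motif database.
#'
#' @return An `mz_motif`.
#' @export
demo_motif <- function() {
  cons <- c("T", "G", "A", "C", "T", "C", "A", "G")
  probs <- t(vapply(cons, function(letter) {
    p <- rep(0.04, 4)
    p[match(letter, DNA_LETTERS)] <- 0.88
    p
  }, numeric(4)))
  motif("PLANT1", probs, name = "synthetic_AP1_like", nsites = 100)
}

#' Random sharp decoy motifs
#'
#' Decoys with one dominant letter per position (probability 0.8), useful as
#' negative controls in ranking experiments.
#'
#' @param n Number of decoys.
#' @param width Motif width (default 8).
#' @param seed Integer seed.
#' @return An `mz_motif_list`.
#' @export
decoy_motifs <- function(n, width = 8L, seed = 1L) {
  gen <- function() {
    lapply(seq_len(n), function(k) {
      cons <- sample(DNA_LETTERS, width, replace = TRUE)
      probs <- t(vapply(cons, function(letter) {
        p <- rep(0.2 / 3, 4)
        p[match(letter, DNA_LETTERS)] <- 0.8
        p
      }, numeric(4)))
      motif(sprintf("DECOY%02d", k), probs,
            name = paste0("decoy_", paste(cons, collapse = "")), nsites = 100)
    })
  }
  as_motif_list(if (is.null(seed)) gen() else withr::with_seed(seed, gen()))
}

#' Paired primary/control fixtures with planted differential signal
#'
#' Emulates a paired treated/untreated design at the study's scale: both sets
#' share the planted motif and occupancy, and differ only in the positional
#' distribution of the planted sites.
#'
#' * `"differential-central"` — primary planted Gaussian (`mu = 0`,
#'   `sigma` bp), control planted uniform: a true differential local signal.
#' * `"null"` — both planted uniform: no positional signal anywhere.
#' * `"swapped"` — roles exchanged (primary uniform, control Gaussian).
#'
#' @param scenario One of `"differential-central"`, `"null"`, `"swapped"`.
#' @param n_seq Sequences per set (default 500).
#' @param L Sequence length in bp (default 500).
#' @param occupancy Planting probability per sequence (default 0.6).
#' @param sigma Gaussian placement sd in bp (default 30).
#' @param motif Planted motif (default [demo_motif()]).
#' @param seed Integer seed; drives all randomness in the fixture.
#' @param dir Optional directory: writes `primary.fa`, `control.fa` and a
#'   tab-separated `truth.tsv` (`set`, `seq_id`, `planted`, `start`,
#'   `strand`).
#' @return A list: `primary` and `control` (`mz_seqset`), `truth` (tibble),
#'   `motif`, and the file paths when `dir` is given.
#' @export
make_paired_fixture <- function(scenario = c("differential-central", "null", "swapped"),
                                n_seq = 500L, L = 500L, occupancy = 0.6,
                                sigma = 30, motif = demo_motif(), seed = 1L,
                                dir = NULL) {
  scenario <- arg_match(scenario)
  placements <- switch(scenario,
    "differential-central" = c("gaussian", "uniform"),
    "null" = c("uniform", "uniform"),
    "swapped" = c("uniform", "gaussian"))
  build <- function() {
    primary <- generate_background_set(n_seq, L, seed = NULL, role = "primary",
                                       prefix = "pri")
    primary <- plant_motifs(primary, motif, occupancy,
                            placement = placements[1L], sigma = sigma,
                            seed = NULL)
    control <- generate_background_set(n_seq, L, seed = NULL, role = "control",
                                       prefix = "ctl")
    control <- plant_motifs(control, motif, occupancy,
                            placement = placements[2L], sigma = sigma,
                            seed = NULL)
    list(primary = primary, control = control)
  }
  sets <- withr::with_seed(seed, build())
  truth <- bind_rows(
    mutate(planted_truth(sets$primary), set = "primary", .before = 1L),
    mutate(planted_truth(sets$control), set = "control", .before = 1L)
  )
  out <- list(primary = sets$primary, control = sets$control, truth = truth,
              motif = motif, scenario = scenario, seed = seed)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    out$primary_path <- file.path(dir, "primary.fa")
    out$control_path <- file.path(dir, "control.fa")
    out$truth_path <- file.path(dir, "truth.tsv")
    write_sequences(sets$primary, out$primary_path)
    write_sequences(sets$control, out$control_path)
    readr::write_tsv(truth, out$truth_path)
  }
  out
}
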