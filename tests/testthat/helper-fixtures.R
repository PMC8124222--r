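# Shared fixtures: small genomes and simulations reused across test files.

# independent sliding-window oracle for MspI cut positions (0-based cut =
# motif index + 1): compares the character array against the motif at every
# offset, never via pattern-matching libraries
oracle_ccgg_cuts <- function(seq) {
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (n < 4L) return(integer(0))
  i <- seq_len(n - 3L)
  hit <- ch[i] == "C" & ch[i + 1L] == "C" & ch[i + 2L] == "G" &
    ch[i + 3L] == "G"
  which(hit)  # 1-based motif index i -> 0-based cut (i - 1) + 1 = i
}

oracle_fragments <- function(seq) {
  cuts <- oracle_ccgg_cuts(seq)
  if (length(cuts) < 2L) return(data.frame(start = integer(), end = integer()))
  data.frame(start = cuts[-length(cuts)], end = cuts[-1L])
}

# sliding-window CG scan (0-based start positions)
oracle_cg_positions <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  which(vapply(seq_len(max(n - 1L, 0L)), function(i) {
    substr(seq, i, i + 1L) == "CG"
  }, logical(1))) - 1L
}

# brute-force two-sided Fisher p by enumeration with choose() ratios
oracle_fisher_p <- function(m1, u1, m2, u2) {
  K <- m1 + m2; N <- m1 + u1 + m2 + u2; r1 <- m1 + u1
  ks <- max(0, K - (N - r1)):min(K, r1)
  pr <- choose(r1, ks) * choose(N - r1, K - ks) / choose(N, K)
  p0 <- pr[ks == m1]
  min(1, sum(pr[pr <= p0 * (1 + 1e-7)]))
}

# one catalogue of two-CpG fragments covering every filter boundary case
filter_fixture <- function() {
  frags <- data.table::data.table(
    contig = "c",
    start = c(0L, 100L, 200L, 300L, 400L, 500L),
    end = c(50L, 150L, 250L, 350L, 450L, 550L),
    fragment_id = sprintf("f%d", 1:6), length = 50L, n_cpgs = 2L)
  cpg_map <- data.table::data.table(
    fragment_id = rep(frags$fragment_id, each = 2L),
    contig = "c", pos = as.integer(c(0, 10, 100, 110, 200, 210, 300, 310,
                                     400, 410, 500, 510)))
  # f1: one CpG only, 50 reads        -> 1 qualifying, fails
  # f2: two CpGs at 9 reads each      -> 0 qualifying, fails
  # f3: two CpGs at 10 reads each     -> 2 qualifying, passes
  # f4: CpGs at 10 and 9 reads        -> 1 qualifying, fails
  # f5: two CpGs at 40 and 12 reads   -> 2 qualifying, passes
  # f6: no coverage                   -> omitted entirely
  calls <- data.table::data.table(
    contig = "c",
    pos = as.integer(c(0, 100, 110, 200, 210, 300, 310, 400, 410)),
    count_M = c(50L, 5L, 0L, 8L, 6L, 10L, 4L, 30L, 12L),
    count_U = c(0L, 4L, 9L, 2L, 4L, 0L, 5L, 10L, 0L))
  list(frags = frags, cpg_map = cpg_map, calls = calls)
}

# small deterministic simulation shared by several files
small_sim <- function(seed = 7L) {
  cfg <- sim_config(seed = seed, n_contigs = 4L, contig_length = 20000L,
                    fragments_per_contig = 40L, n_planted_dmf = 20L)
  art <- generate_genome(cfg)
  pairs <- lapply(seq_len(cfg$n_pairs), function(p) simulate_pair(art, p))
  list(cfg = cfg, art = art, pairs = pairs)
}

# aggregate all four samples of a simulation against its catalogue
aggregate_sim <- function(sim) {
  cpg_map <- fragment_cpgs(sim$art$seqs, sim$art$in_window)
  out <- list()
  for (p in seq_along(sim$pairs)) {
    for (s in c("tissue", "cell")) {
      nm <- sprintf("pair%d_%s", p, s)
      out[[nm]] <- aggregate_fragments(sim$art$in_window, cpg_map,
                                       read_cpg_calls(sim$pairs[[p]][[s]]))
    }
  }
  out
}
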