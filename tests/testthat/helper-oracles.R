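# Brute-force oracles and small random-sequence generators used by the
# property-style tests. The oracles are deliberately naive loops, kept
# independent of the package's regex-based scanners.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_aa_seq <- function(len, p_proline = 0.15) {
  prob <- rep((1 - p_proline) / 19, 20)
  prob[AA20 == "P"] <- p_proline
  paste(sample(AA20, len, replace = TRUE, prob = prob), collapse = "")
}

# every 1-based start i of an in-bounds 4-residue window whose middle two
# residues are proline
oracle_xppx_positions <- function(sequence) {
  ch <- strsplit(sequence, "")[[1]]
  n <- length(ch)
  if (n < 4) return(integer(0))
  which(vapply(seq_len(n - 3), function(i) {
    ch[i + 1] == "P" && ch[i + 2] == "P"
  }, logical(1)))
}

oracle_triplet_positions <- function(sequence, triplets) {
  ch <- strsplit(sequence, "")[[1]]
  n <- length(ch)
  if (n < 3) return(integer(0))
  sort(which(vapply(seq_len(n - 2), function(i) {
    paste(ch[i:(i + 2)], collapse = "") %in% triplets
  }, logical(1))))
}

# all-pairs distance check for stall-atlas support
oracle_stall_support <- function(hit_pos, atlas_pos, window) {
  out <- FALSE
  for (h in hit_pos) {
    for (a in atlas_pos) {
      if (abs(h - a) <= window) out <- TRUE
    }
  }
  out
}
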