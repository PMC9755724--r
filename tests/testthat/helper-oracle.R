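# Independent brute-force oracle: enumerate every global alignment (all
# interleavings of match / gap-in-b / gap-in-a columns, no double-gap
# columns) and score it with affine gap runs; terminal runs are free unless
# the scheme penalizes end gaps. Exponential, so only for tiny sequences.
brute_force_align_score <- function(a, b, scheme) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  S <- scheme$matrix
  open <- scheme$gap_open; ext <- scheme$gap_extend
  free_ends <- !scheme$penalize_end_gaps
  m <- length(A); n <- length(B)
  best <- -Inf
  types <- character(m + n)
  rec <- function(i, j, k, msum) {
    if (i > m && j > n) {
      r <- rle(types[seq_len(k)])
      gcost <- 0
      for (q in seq_along(r$values)) {
        if (r$values[q] == "m") next
        if (free_ends && (q == 1 || q == length(r$values))) next
        gcost <- gcost + open + (r$lengths[q] - 1) * ext
      }
      if (msum - gcost > best) best <<- msum - gcost
      return(invisible())
    }
    if (i <= m && j <= n) {
      types[k + 1] <<- "m"
      rec(i + 1, j + 1, k + 1, msum + S[A[i], B[j]])
    }
    if (i <= m) { types[k + 1] <<- "a"; rec(i + 1, j, k + 1, msum) }
    if (j <= n) { types[k + 1] <<- "b"; rec(i, j + 1, k + 1, msum) }
  }
  rec(1L, 1L, 0L, 0)
  best
}

AA20_TEST <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_aa <- function(n) paste(sample(AA20_TEST, n, replace = TRUE),
                               collapse = "")

# apply exactly k substitutions (to a different residue) at distinct sites
mutate_k <- function(seq, k) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample(length(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(AA20_TEST, ch[p]), 1)
  paste(ch, collapse = "")
}
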