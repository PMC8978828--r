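# --- brute-force spanning tree enumeration via Prufer sequences ------------
# all n^(n-2) labeled trees on `taxa`; returns the maximal total weight
prufer_max_weight <- function(taxa, weight_of) {
  d <- length(taxa)
  seqs <- expand.grid(rep(list(seq_len(d)), d - 2))
  best <- -Inf
  for (r in seq_len(nrow(seqs))) {
    pr <- as.integer(seqs[r, ])
    degree <- rep(1L, d)
    for (v in pr) degree[v] <- degree[v] + 1L
    edges <- matrix(0L, d - 1, 2)
    avail <- degree
    prs <- pr
    for (e in seq_len(d - 2)) {
      leaf <- min(which(avail == 1L))
      edges[e, ] <- c(leaf, prs[1L])
      avail[leaf] <- 0L
      avail[prs[1L]] <- avail[prs[1L]] - 1L
      prs <- prs[-1L]
    }
    edges[d - 1, ] <- which(avail == 1L)
    w <- sum(vapply(seq_len(d - 1),
                    function(e) weight_of(taxa[edges[e, 1]], taxa[edges[e, 2]]),
                    numeric(1)))
    if (w > best) best <- w
  }
  best
}
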