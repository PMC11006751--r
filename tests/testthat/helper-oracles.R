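# Independent statistical oracles used across test files.

# step-by-step two-stage BH oracle, written straight from the definition:
# stage 1 is Benjamini-Hochberg at q/(1+q); if it rejects none or all, stop;
# otherwise rerun BH at q/(1+q) * m / (m - r1).
bky_oracle <- function(p, q = 0.05) {
  m <- length(p)
  qp <- q / (1 + q)
  bh_reject <- function(pv, level) {
    o <- order(pv)
    s <- pv[o]
    below <- which(s <= level * seq_len(m) / m)
    r <- if (length(below)) max(below) else 0L
    rej <- rep(FALSE, m)
    if (r > 0) rej[o[seq_len(r)]] <- TRUE
    rej
  }
  r1 <- sum(bh_reject(p, qp))
  if (r1 == 0L) return(rep(FALSE, m))
  if (r1 == m) return(rep(TRUE, m))
  bh_reject(p, qp * m / (m - r1))
}
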