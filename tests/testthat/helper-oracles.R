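# Independent brute-force oracles for the detection metrics.

bruteAuc <- function(scores, pos) {
  s <- 0
  for (i in which(pos)) for (j in which(!pos)) {
    s <- s + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  s / (sum(pos) * sum(!pos))
}

bruteFpr <- function(scores, pos, sens = 0.95) {
  best <- NULL
  for (th in sort(unique(scores[pos]), decreasing = TRUE)) {
    if (mean(scores[pos] >= th) >= sens) {
      best <- th
      break
    }
  }
  if (is.null(best)) return(1)
  mean(scores[!pos] >= best)
}
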