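# tiny synthetic feature store: 2 conditions x trials x 3 channels x 2 labels
make_store <- function(n_per_class = 12, sep = 0, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (cond in c("right", "rest")) {
    mu <- if (cond == "right") sep else 0
    for (tr in seq_len(n_per_class)) {
      for (ch in c("C3", "Cz", "C4")) {
        for (t in c(0, 0.1)) {
          r <- data.frame(trial = tr + (cond == "rest") * 1000,
                          condition = cond, channel = ch, t = t,
                          H = rnorm(1, 0.6 + mu * 0.1), d = rnorm(1, mu * 0.1),
                          erd = rnorm(1, -20 * mu), band_power = 1)
          for (k in 1:10) r[[paste0("phi", k)]] <- rnorm(1, mu * 0.05)
          rows[[length(rows) + 1]] <- r
        }
      }
    }
  }
  do.call(rbind, rows)
}
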