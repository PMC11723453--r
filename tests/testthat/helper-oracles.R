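# Naive single-loop reference implementations used as independent oracles.

naive_mae <- function(M, E) {
  s <- 0; C <- nrow(M); T <- ncol(M)
  for (c in seq_len(C)) for (t in seq_len(T)) s <- s + abs(M[c, t] - E[c, t])
  s / (C * T)
}

naive_cmae <- function(M, E) {
  C <- nrow(M); T <- ncol(M); s <- 0
  for (t in seq_len(T)) {
    acc <- 0
    for (c in seq_len(C)) acc <- acc + (M[c, t] - E[c, t])
    s <- s + abs(acc)
  }
  s / (C * T)
}

naive_trapz <- function(y) {
  s <- 0
  for (i in seq_len(length(y) - 1)) s <- s + (y[i] + y[i + 1]) / 2
  s
}

naive_determinants <- function(x) {
  k <- 1
  for (i in seq_along(x)) if (x[i] > x[k]) k <- i
  list(T2P = 100 * (k - 1) / (length(x) - 1),
       M2P = 100 * mean(x) / x[k],
       WR = 100 * (if (k == 1) 0 else naive_trapz(x[1:k])) / naive_trapz(x))
}

naive_drive_scan <- function(force, on_N = 196.2, off_N = 98.1) {
  start <- NA
  for (i in seq_along(force)) if (force[i] > on_N) { start <- i; break }
  if (is.na(start)) return(NULL)
  end <- length(force) + 1
  for (i in start:length(force)) if (force[i] < off_N) { end <- i; break }
  list(drive_start_idx = start - 1, drive_end_idx = end - 1)
}

# Eq.-by-eq samplewise oracle for the gate power
naive_gate_power <- function(theta, theta_dot, Fx, Fy, li) {
  out <- numeric(length(theta$port))
  for (i in seq_along(out)) {
    for (s in c("port", "starboard")) {
      out[i] <- out[i] + (Fx[[s]][i] * li * cos(theta[[s]][i]) +
                          Fy[[s]][i] * li * sin(theta[[s]][i])) * theta_dot[[s]][i]
    }
  }
  out
}
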