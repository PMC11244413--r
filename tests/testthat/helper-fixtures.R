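# Small fixtures built in code.

# minimal valid wide-format plot data.frame (3 plots, exact additivity)
tiny_plot_df <- function() {
  data.frame(
    plot_id = c("p1", "p2", "p3"),
    si_P = c(14, 15, 16), adbh_P = c(25, 30, 35), sdi_P = c(400, 450, 500),
    sba_P = c(10, 12, 14),
    si_B = c(14.5, 15.5, 16.5), adbh_B = c(27, 31, 36),
    sdi_B = c(200, 240, 280), sba_B = c(5, 6, 7),
    si_t = c(14.2, 15.2, 16.2), adbh_t = c(26, 30.5, 35.5),
    sdi_t = c(600, 690, 780), sba_t = c(15, 18, 21),
    stringsAsFactors = FALSE)
}

# reference coefficient shorthands used across tests
truth_nsur_P <- c(30.3645, 0.2701, 0.0002, 6.6979, 0.1498)  # Richards M6
truth_nsur_B <- c(0.0080, 0.4216, 1.4756, 1.0338)           # Korf M1
truth_ap_P <- c(19.254, 0.307, 0.003, 6.808, 0.157)
truth_ap_B <- c(0.010, 0.377, 3.343, 1.032)
truth_ap_t <- c(0.016, 0.264, 3.155, 1.001)
mean_cov_B <- list(si = 14.8, adbh = 29, sdi = 242.7)

# independent hand-coded evaluation of the extended Korf form (M1),
# used as a second implementation against sba_eval
m1_by_hand <- function(b, si, adbh, sdi)
  b[1] * si^b[2] * exp(-b[3] / adbh) * sdi^b[4]

# independent brute-force oracle for the 2-parameter Schumacher base:
# dense 2-D grid search, repeatedly zoomed around the incumbent minimum
grid_search_schumacher <- function(y, t_, b0_range, b1_range,
                                   n_grid = 61, n_zoom = 10) {
  sse <- function(b0, b1) {
    pred <- outer(b0, rep(1, length(t_))) *
      exp(-outer(b1, 1 / t_, `*`))
    rowSums((matrix(y, length(b0), length(y), byrow = TRUE) - pred)^2)
  }
  for (z in seq_len(n_zoom)) {
    g <- expand.grid(b0 = seq(b0_range[1], b0_range[2], length.out = n_grid),
                     b1 = seq(b1_range[1], b1_range[2], length.out = n_grid))
    vals <- sse(g$b0, g$b1)
    best <- g[which.min(vals), ]
    w0 <- diff(b0_range) / (n_grid - 1)
    w1 <- diff(b1_range) / (n_grid - 1)
    b0_range <- c(best$b0 - 2 * w0, best$b0 + 2 * w0)
    b1_range <- c(max(0, best$b1 - 2 * w1), best$b1 + 2 * w1)
  }
  min(vals)
}
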