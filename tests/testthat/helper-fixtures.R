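# Shared fixtures, built in code at test time.

# Synthetic stand-in for the published median pickup curve: bins 40..72 mm
# hold constant precipitation values, anchored at the three printed medians
# (0.4 mm/h at 60 mm, 1.5 at 65, 10.2 at 70) with exponential interpolation
# between anchors. Constant-valued bins make all three quartiles exact.
fig2_fixture_curve <- function() {
  bins <- 40:72
  anchors <- data.frame(w = c(40, 60, 65, 70, 72),
                        p = c(0.005, 0.4, 1.5, 10.2, 25))
  p50 <- exp(approx(anchors$w, log(anchors$p), xout = bins)$y)
  data <- data.frame(
    cwv = rep(bins + 0.5, each = 7),
    precip = rep(p50, each = 7)
  )
  build_quantile_curve(data)
}

# Small default-parameter synthetic data set (one seed, memoized per session).
small_climate <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      grid <- make_grid(0, 0.5, 0, 0.5, 0.25)
      cache <<- simulate_climate(grid, n_hours = 8760, seed = 42)
    }
    cache
  }
})

# Independent brute-force oracle for the binned quartile curve: sorts each
# bin and interpolates order statistics directly (no call to quantile()).
brute_force_curve <- function(cwv, precip, bin_width = 1, min_count = 6,
                              max_cwv = 73) {
  keep <- cwv < max_cwv
  cwv <- cwv[keep]
  precip <- precip[keep]
  interp_q <- function(x, q) {
    x <- sort(x)
    n <- length(x)
    if (n == 1) return(x)
    h <- (n - 1) * q
    lo <- floor(h)
    x[lo + 1] + (h - lo) * (x[lo + 2 - (lo == n - 1)] - x[lo + 1])
  }
  lowers <- sort(unique(floor(cwv / bin_width) * bin_width))
  rows <- lapply(lowers, function(k) {
    p <- precip[floor(cwv / bin_width) * bin_width == k]
    data.frame(bin_lower = k, count = length(p),
               p25 = interp_q(p, 0.25), p50 = interp_q(p, 0.50),
               p75 = interp_q(p, 0.75), valid = length(p) >= min_count)
  })
  do.call(rbind, rows)
}
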