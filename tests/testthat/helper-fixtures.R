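# shared fixture builders; everything is generated in code

# a minimal 2-scatter + 2-fluorescence panel for arithmetic examples
toy_panel <- function() {
  panel_definition("T1", data.frame(
    name = c("FS", "SS", "FL1", "FL2"),
    marker = c("FS", "SS", "CD3", "CD4"),
    kind = c("scatter", "scatter", "fluorescence", "fluorescence"),
    stringsAsFactors = FALSE))
}

toy_matrix <- function(n = 100, panel = toy_panel(), seed = 1) {
  set.seed(seed)
  matrix(runif(n * n_channels(panel), 0, 1000), nrow = n)
}

# hand-built gate tree on the toy panel: leaf In = CD3/CD4 double-high,
# leaf Out = everything else
toy_tree <- function(panel = toy_panel(), x_lo = 3, y_lo = 3) {
  g <- gate2d("CD3", "CD4", x_lo, 6, y_lo, 6)
  pop_in <- population_definition("T1C0001", "T1",
                                  list(list(gate = g, side = "inside")),
                                  "underrepresented_in_ttf1")
  pop_out <- population_definition("T1C0002", "T1",
                                   list(list(gate = g, side = "outside")),
                                   "overrepresented_in_ttf1")
  root <- list(type = "split", gate = g, d = 0,
               inside = list(type = "leaf", pop_id = "T1C0001"),
               outside = list(type = "leaf", pop_id = "T1C0002"))
  structure(list(tube = "T1", panel = panel, root = root,
                 leaves = list(pop_in, pop_out),
                 training_config = discovery_config()),
            class = "gate_tree")
}

# small planted cohort for integration tests (standardized output skips
# the preprocessing cost where it is not the subject under test)
small_cohort <- function(n1 = 12, n0 = 20, events = 2000, seed = 5,
                         output = "standardized", null = FALSE,
                         tubes = "T1") {
  generate_cohort(cohort_config(n_ttf1 = n1, n_ttf0 = n0,
                                events_per_sample = events, tubes = tubes,
                                output = output, null = null, seed = seed))
}

# independent brute-force oracle for the ABC partition: scan every A/B
# boundary for the minimum distance to (0, 1), then every B/C boundary
# for the first break-even item
abc_oracle <- function(values) {
  v <- sort(values, decreasing = TRUE)
  n <- length(v)
  cum <- cumsum(v) / sum(v)
  best <- Inf; i_ab <- NA
  for (i in 1:n) {
    di <- sqrt((i / n)^2 + (1 - cum[i])^2)
    if (di < best) { best <- di; i_ab <- i }
  }
  i_bc <- n
  if (i_ab < n) for (i in (i_ab + 1):n) {
    if (v[i] <= mean(v[i:n]) + 1e-12) { i_bc <- i; break }
  } else i_bc <- i_ab
  list(a_b = i_ab, b_c = i_bc)
}

# exact two-sided Mann-Whitney p by full enumeration of group
# assignments (small n, no ties)
mwu_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_of <- function(xs, ys) sum(outer(xs, ys, ">"))
  u_obs <- u_of(x, y)
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  # two-sided: double the smaller tail (the convention of the exact
  # Wilcoxon distribution)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  list(U = u_obs, p = min(p, 1))
}
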