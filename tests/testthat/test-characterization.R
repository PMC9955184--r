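# build one standardized sample directly from the phenotype templates
template_sample <- function(pops, n_each = 600, tube = "T1", seed = 1) {
  set.seed(seed)
  tpl <- population_templates(tube)
  panel <- cll_panel(tube)
  blocks <- lapply(pops, function(p) {
    m <- tpl[[p]]$mean; s <- tpl[[p]]$sd
    v <- matrix(rnorm(n_each * length(m), rep(m, each = n_each),
                      rep(s, each = n_each)), n_each)
    pmin(pmax(v, 0), 6)
  })
  event_matrix(do.call(rbind, blocks), panel, "tplsample",
               "standardized")
}

# a manual tree whose inside leaf is the given forward-scatter window
fs_tree <- function(lo, hi) {
  panel <- cll_panel("T1")
  g <- gate2d("FS", "SS", lo, hi, 0, 6)
  root <- list(type = "split", gate = g, d = 0,
               inside = list(type = "leaf", pop_id = "T1C0001"),
               outside = list(type = "leaf", pop_id = "T1C0002"))
  structure(list(
    tube = "T1", panel = panel, root = root,
    leaves = list(
      population_definition("T1C0001", "T1",
                            list(list(gate = g, side = "inside")),
                            "overrepresented_in_ttf1"),
      population_definition("T1C0002", "T1",
                            list(list(gate = g, side = "outside")),
                            "underrepresented_in_ttf1")),
    training_config = discovery_config()), class = "gate_tree")
}

test_that("a population matching the reference CLL gate has null deltas", {
  tree <- fs_tree(0, 6)
  # a pure CLL sample pooled whole must produce near-zero deltas
  pure <- template_sample("CLL", seed = 3)
  prof_pure <- population_profile(tree, list(s1 = pure), "T1C0001",
                                  reference_rule = c(CD19 = 3, CD5 = 3))
  expect_lt(max(abs(prof_pure$delta)), 0.25)
  expect_false(prof_pure$low_fsc)
  expect_false(prof_pure$high_fsc)
})

test_that("apoptotic-like populations show dim scatter and antigens", {
  em <- template_sample(c("CLL", "CLL_apoptotic"), seed = 5)
  tree <- fs_tree(0, 1.8)   # low-FS window isolates the apoptotic mode
  prof <- population_profile(tree, list(s1 = em), "T1C0001",
                             reference_rule = c(CD19 = 3, CD5 = 3))
  expect_lt(prof$delta[["FS"]], -0.5)
  expect_true(prof$low_fsc)
  for (ch in c("CD19", "CD5", "CD23"))
    expect_lt(prof$delta[[ch]], 0)
})

test_that("prolymphocytoid-like populations show bright scatter/antigens", {
  em <- template_sample(c("CLL", "CLL_prolymphocytoid"), seed = 6)
  tree <- fs_tree(3.3, 6)
  prof <- population_profile(tree, list(s1 = em), "T1C0001",
                             reference_rule = c(CD19 = 3, CD5 = 3))
  expect_gt(prof$delta[["FS"]], 0.5)
  expect_true(prof$high_fsc)
  expect_gt(prof$delta[["SS"]], 0)
  for (ch in c("CD19", "CD23"))
    expect_gt(prof$delta[[ch]], 0)
})

test_that("lineage annotation recovers every unambiguous template", {
  tpl <- population_templates("T1")
  call_for <- function(name) {
    prof <- structure(list(pop_id = name, median = tpl[[name]]$mean,
                           reference = tpl$CLL$mean,
                           delta = tpl[[name]]$mean - tpl$CLL$mean,
                           n_events = 1000, low_fsc = FALSE,
                           high_fsc = FALSE),
                      class = "population_profile")
    annotate_lineage(prof)
  }
  expect_equal(call_for("T_CD4")$label, "T_CD4")
  expect_equal(call_for("T_CD8")$label, "T_CD8")
  expect_equal(call_for("CLL")$label, "CLL_subset")
  expect_equal(call_for("CLL_prolymphocytoid")$label, "CLL_subset")
  expect_equal(call_for("NK")$label, "NK_or_T_mix")
  expect_equal(call_for("other")$label, "other")
  # every fired call carries its rule trace
  expect_gt(nrow(call_for("T_CD4")$rule_trace), 0)
  expect_equal(nrow(call_for("other")$rule_trace), 0)
})

test_that("profiles straddling the rules are called mixed with a trace", {
  med <- population_templates("T1")$CLL$mean
  med["CD19"] <- 3.5; med["CD5"] <- 1.0; med["CD3"] <- 3.5
  med["CD4"] <- 1.0; med["CD8"] <- 1.0; med["CD7"] <- 1.0
  prof <- structure(list(pop_id = "x", median = med, reference = med,
                         delta = med * 0, n_events = 100,
                         low_fsc = FALSE, high_fsc = FALSE),
                    class = "population_profile")
  call <- annotate_lineage(prof)
  expect_equal(call$label, "mixed")
  expect_gt(nrow(call$rule_trace), 0)
})

test_that("annotation refuses profiles lacking lineage channels", {
  tpl2 <- population_templates("T2")$CLL
  prof <- structure(list(pop_id = "t2", median = tpl2$mean,
                         reference = tpl2$mean, delta = tpl2$mean * 0,
                         n_events = 100, low_fsc = FALSE,
                         high_fsc = FALSE),
                    class = "population_profile")
  expect_error(annotate_lineage(prof), "lineage channel")
})

test_that("dot plot export draws the populations it is asked for", {
  em <- template_sample(c("CLL", "T_CD4"), n_each = 400, seed = 9)
  tree <- toy_tree(cll_panel("T1"))
  dir <- file.path(tempdir(), "dotplots")
  paths <- export_dotplots(em, tree, "T1C0001",
                           list(c("CD3", "CD4")), dir = dir)
  expect_true(file.exists(paths[1]))
  expect_gt(file.size(paths[1]), 1000)
  # overlay count equals the frequency-table count for that population
  ft <- frequency_table(tree, list(s = em))
  n_overlay <- sum(assign_events(tree, em) == "T1C0001")
  expect_equal(ft$T1C0001 * nrow(em$values) / 100, n_overlay)
  expect_error(export_dotplots(em, tree, "T1C0001",
                               list(c("CD3", "CD99"))), "not in panel")
})

test_that("tiny populations are rejected for profiling", {
  em <- template_sample("CLL", n_each = 300, seed = 10)
  tree <- fs_tree(5.9, 6)   # essentially empty window
  expect_error(population_profile(tree, list(s1 = em), "T1C0001",
                                  reference_rule = c(CD19 = 3, CD5 = 3)),
               "fewer than")
})
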