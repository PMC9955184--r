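#' Phenotype templates for the synthetic CLL cohort
#'
#' Each template names one cell population and gives, per panel channel, a
#' mean and standard deviation of expression on the standardized `[0,6]`
#' scale.  The defaults encode the lineage phenotypes a clinical
#' cytometrist expects in a CLL peripheral-blood sample:
#'
#' * `CLL` — CD19+ CD5+ CD23+ CD200+ CD43+, dim CD20/CD79b/FMC7/IgM, a
#'   single dominant light chain (clonality; which chain is drawn per
#'   sample).
#' * `CLL_apoptotic` — the CLL phenotype with low forward scatter and all
#'   antigens uniformly dimmed (apoptotic/dead CLL events).
#' * `CLL_prolymphocytoid` — the converse: higher forward/side scatter and
#'   brighter antigen expression, FMC7 partially positive.
#' * `T_CD4`, `T_CD8` — CD3+ CD5+ CD2+ CD7+ T cells split by CD4/CD8.
#' * `NK` — CD3- CD2+ CD7+ lymphocytes with dim CD8.
#' * `other` — residual non-lymphoid events (monocytes, debris).
#'
#' @param tube `"T1"` or `"T2"`.
#' @return Named list of templates; each has `mean` and `sd` vectors over
#'   the tube's channels (marker names).
#' @export
population_templates <- function(tube = c("T1", "T2")) {
  tube <- match.arg(tube)
  panel <- cll_panel(tube)
  markers <- panel$channels$marker

  base_sd <- stats::setNames(rep(0.5, length(markers)), markers)
  base_sd[c("FS", "SS")] <- 0.6

  tpl <- function(means) {
    m <- stats::setNames(rep(0.8, length(markers)), markers)
    m[names(means)] <- means
    list(mean = pmin(pmax(m, 0), 6), sd = base_sd)
  }

  if (tube == "T1") {
    cll <- tpl(c(FS = 2.5, SS = 1.8, CD19 = 4.5, CD20 = 2.3, FMC7 = 1.0,
                 CD79b = 1.2, CD23 = 4.0, kappa = 2.8, lambda = 0.7,
                 CD3 = 0.8, CD5 = 4.2, CD2 = 1.0, CD7 = 0.8,
                 CD4 = 0.8, CD8 = 0.8, CD38 = 1.6))
    t4 <- tpl(c(FS = 2.8, SS = 1.5, CD3 = 4.5, CD5 = 4.3, CD2 = 4.2,
                CD7 = 4.0, CD4 = 4.5, CD8 = 0.8, CD38 = 1.5))
    t8 <- tpl(c(FS = 2.8, SS = 1.5, CD3 = 4.5, CD5 = 4.2, CD2 = 4.2,
                CD7 = 4.1, CD4 = 0.8, CD8 = 4.5, CD38 = 1.8))
    nk <- tpl(c(FS = 3.0, SS = 1.7, CD3 = 0.8, CD2 = 3.8, CD7 = 4.2,
                CD8 = 2.0, CD38 = 2.5))
    oth <- tpl(c(FS = 3.4, SS = 3.0, CD4 = 1.8, CD38 = 2.0))
  } else {
    cll <- tpl(c(FS = 2.5, SS = 1.8, CD19 = 4.5, CD20 = 2.3, IgM = 1.4,
                 CD103 = 0.8, CD11c = 1.2, CD25 = 1.8, CD10 = 0.8,
                 CD43 = 4.0, CD200 = 4.5))
    t4 <- tpl(c(FS = 2.8, SS = 1.5, CD43 = 3.8))
    t8 <- tpl(c(FS = 2.8, SS = 1.5, CD43 = 3.8))
    nk <- tpl(c(FS = 3.0, SS = 1.7, CD11c = 1.5))
    oth <- tpl(c(FS = 3.4, SS = 3.0, CD11c = 2.2))
  }

  # apoptotic: FS pulled low, fluorescence dimmed; prolymphocytoid: the
  # converse with brighter antigens and larger scatter
  fl <- markers[panel$channels$kind == "fluorescence"]
  apo <- cll
  apo$mean["FS"] <- 1.1
  apo$mean[fl] <- pmax(cll$mean[fl] * 0.55, 0.3)
  pro <- cll
  pro$mean["FS"] <- 3.9
  pro$mean["SS"] <- 2.7
  pro$mean[fl] <- pmin(cll$mean[fl] * 1.3 + 0.3, 6)
  if (tube == "T1") pro$mean["FMC7"] <- 2.4

  list(CLL = cll, CLL_apoptotic = apo, CLL_prolymphocytoid = pro,
       T_CD4 = t4, T_CD8 = t8, NK = nk, other = oth)
}
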