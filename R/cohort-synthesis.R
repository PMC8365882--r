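# Synthetic two-species descriptor cohorts with prescribed medians and
# multiplicative spreads (log-normal), for exercising the group
# comparison machinery with known ground truth.

#' Descriptor column names of a cohort table
#' @return character vector of the 15 per-vessel descriptor columns.
#' @export
descriptorNames <- function() {
  c("tawss", "osi", "rrt", "transwss",
    "h1", "h2", "h3", "h4",
    "q_mean", "q_peak", "q_ptp",
    "kappa_mean", "tau_mean", "dm", "si_mean")
}

# descriptors that may legitimately be negative (signed balances / net
# helicity); all others are positive-only
signedDescriptors <- function() c("h1", "h3")

#' Default cohort design
#'
#' Per species x vessel x descriptor target medians and multiplicative
#' spreads (log scale SD). Medians are set to physiologically plausible
#' coronary values: OSI and helicity intensity differ between species in
#' the vessels where a real inter-species contrast is expected (swine
#' LAD higher OSI and inflow peaks; human RCA/LCX higher h2; human
#' sections more eccentric, i.e. lower SI), all other descriptors share
#' medians across species.
#'
#' @return data.frame with columns `species`, `vessel_type`,
#'   `descriptor`, `median`, `sdlog`.
#' @export
defaultCohortDesign <- function() {
  vessels <- c("RCA", "LAD", "LCX")
  species <- c("human", "swine")
  base <- list(
    tawss = c(1.5, 0.4), osi = c(5e-4, 0.6), rrt = c(0.7, 0.4),
    transwss = c(0.03, 0.5),
    h1 = c(0.15, 0.6), h2 = c(1.8, 0.6), h3 = c(0.1, 0.5), h4 = c(0.3, 0.5),
    q_mean = c(1.0e-5, 0.4), q_peak = c(2.5e-5, 0.4), q_ptp = c(2.0e-6, 0.4),
    kappa_mean = c(0.1, 0.3), tau_mean = c(0.15, 0.4),
    dm = c(1.08, 0.03), si_mean = c(0.85, 0.08)
  )
  g <- expand.grid(species = species, vessel_type = vessels,
                   descriptor = names(base),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$median <- vapply(g$descriptor, function(d) base[[d]][1], numeric(1))
  g$sdlog <- vapply(g$descriptor, function(d) base[[d]][2], numeric(1))
  set_ <- function(sp, ve, de, med, sdl = NULL) {
    i <- g$species == sp & g$vessel_type == ve & g$descriptor == de
    g$median[i] <<- med
    if (!is.null(sdl)) g$sdlog[i] <<- sdl
  }
  # species contrasts
  set_("swine", "LAD", "osi", 2.3e-3, 1.0)
  set_("swine", "RCA", "osi", 9e-4); set_("swine", "LCX", "osi", 9e-4)
  set_("human", "RCA", "h2", 2.53); set_("human", "LCX", "h2", 2.33)
  set_("swine", "RCA", "h2", 0.71); set_("swine", "LCX", "h2", 0.46)
  set_("swine", "LAD", "h2", 0.9)
  set_("swine", "LAD", "q_peak", 5.2e-5)
  set_("swine", "LAD", "q_ptp", 4.97e-6)
  set_("human", "LAD", "q_ptp", 1.86e-6)
  for (v in vessels) {
    set_("human", v, "si_mean", 0.77)
    set_("swine", v, "si_mean", 0.88)
  }
  set_("human", "RCA", "dm", 1.15, 0.05); set_("swine", "RCA", "dm", 1.15, 0.05)
  g
}

#' Generate a synthetic cohort descriptor table
#'
#' Samples each descriptor for each species x vessel group from a
#' log-normal distribution parameterized by its target median m and
#' multiplicative spread: `x = m * exp(sdlog * Z)`, `Z ~ N(0,1)` (so the
#' population median is exactly m and `sdlog = 0` collapses to the
#' median). Signed descriptors (h1, h3) keep the sign of their median
#' and sample the magnitude the same way.
#'
#' @param design a design data.frame as from [defaultCohortDesign()].
#' @param nPerGroup vessels per species x vessel cell (>= 3).
#' @param seed integer seed; the table is reproducible bit-for-bit.
#' @return data.frame with `vessel_id`, `species`, `vessel_type` and the
#'   15 descriptor columns.
#' @export
makeCohort <- function(design = defaultCohortDesign(), nPerGroup = 10, seed = 1) {
  if (nPerGroup < 3) stopParameter("nPerGroup must be >= 3")
  if (any(design$sdlog < 0)) stopParameter("dispersions must be non-negative")
  pos <- setdiff(unique(design$descriptor), signedDescriptors())
  bad <- design$descriptor %in% pos & design$median <= 0
  if (any(bad))
    stopParameter("non-positive median for positive-only descriptor(s): %s",
                  paste(unique(design$descriptor[bad]), collapse = ", "))
  set.seed(seed)
  cells <- unique(design[, c("species", "vessel_type")])
  rows <- list()
  for (ci in seq_len(nrow(cells))) {
    sp <- cells$species[ci]; ve <- cells$vessel_type[ci]
    d <- data.frame(
      vessel_id = sprintf("%s_%s_%02d", sp, ve, seq_len(nPerGroup)),
      species = sp, vessel_type = ve, stringsAsFactors = FALSE)
    sub <- design[design$species == sp & design$vessel_type == ve, ]
    for (de in descriptorNames()) {
      r <- sub[sub$descriptor == de, ]
      if (nrow(r) != 1) stopParameter("design must have exactly one row per cell x descriptor (%s/%s/%s)", sp, ve, de)
      z <- rnorm(nPerGroup)
      d[[de]] <- sign(r$median) * abs(r$median) * exp(r$sdlog * z)
    }
    rows[[ci]] <- d
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
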