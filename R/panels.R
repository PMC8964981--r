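# Default antibody panels and phenotype gating rules.
#
# The two-panel design mirrors a common CyTOF immunome setup: panel P1 is
# T/NK-focused, panel P2 is B/myeloid-focused; both share a backbone of
# lineage and cytokine markers so major lineages are identifiable in either.

.shared_markers <- c(
  "CD3", "CD4", "CD8", "CD19", "CD56", "CD14", "CD16", "CD11c", "HLADR",
  "CD45RA", "CD45RO", "CD25", "CD161", "CCR2", "CXCR3", "TNFa", "IFNg",
  "IL6", "IL10"
)

.p1_only <- c(
  "Va72", "FOXP3", "CD28", "CD69", "CD154", "CD27", "CCR7", "CD62L",
  "CCR6", "CCR4", "CD103", "GZMB", "IL21", "IL17A", "IL22", "IL4", "PD1"
)

.p2_only <- c(
  "IgD", "IgM", "CD24", "CD20", "CD38", "TLR4", "CD11b", "CXCR5", "CD31",
  "cMet", "AGTR2", "HMGB1", "MIP1b", "IL8", "IL1b", "TGFb", "CD223"
)

#' Construct a panel specification
#'
#' @param panel_id Panel label (e.g. `"P1"`).
#' @param marker_names Ordered character vector of unique marker names.
#' @param shared_markers Markers common to both panels of the study design.
#' @return A `panel_spec` list with fields `panel_id`, `marker_names`,
#'   `shared_markers`.
#' @export
panel_spec <- function(panel_id, marker_names, shared_markers = character()) {
  if (anyDuplicated(marker_names)) {
    abort("marker names must be unique within a panel")
  }
  if (!all(shared_markers %in% marker_names)) {
    abort("shared_markers must be a subset of marker_names")
  }
  structure(
    list(panel_id = panel_id, marker_names = marker_names,
         shared_markers = shared_markers),
    class = "panel_spec"
  )
}

#' Default two-panel design: 36 markers each, 19 shared
#'
#' Panel `P1` carries T/NK markers (TCR V-alpha-7.2, FOXP3, activation and
#' trafficking receptors, T/NK cytokines); panel `P2` carries B/myeloid
#' markers (immunoglobulins, CD20/CD24/CD38, TLR4, myeloid cytokines). The
#' 19-marker shared backbone covers the major lineage markers.
#'
#' @return Named list of two `panel_spec` objects (`P1`, `P2`).
#' @export
default_panels <- function() {
  list(
    P1 = panel_spec("P1", c(.shared_markers, .p1_only), .shared_markers),
    P2 = panel_spec("P2", c(.shared_markers, .p2_only), .shared_markers)
  )
}

#' Default lineage gating table
#'
#' Ordered marker-pattern rules mapping node phenotypes to major immune
#' lineages; rules are evaluated top to bottom and the first match wins,
#' unmatched nodes fall through to `"other"`. A marker is called positive
#' when its scaled median exceeds the positivity threshold (default 0, i.e.
#' above the across-node average). Patterns: Treg CD3+CD4+CD25+FOXP3+;
#' MAIT CD3+Va7.2+CD161+; CD4T CD3+CD4+CD8-; CD8T CD3+CD8+; otherT CD3+;
#' NK CD3-CD56+; B CD19+ (CD3-); MonoDC CD3-CD19- with any of
#' CD14/CD16/CD11c positive.
#'
#' @param markers Optional character vector of the panel's markers; rules
#'   that reference markers absent from the panel are dropped (e.g. the
#'   FOXP3-based Treg rule on a panel without FOXP3).
#' @return A tibble with columns `lineage`, `positive`, `negative`,
#'   `any_positive` (list-columns of marker names).
#' @export
default_gating_table <- function(markers = NULL) {
  rules <- tribble(
    ~lineage,  ~positive,                              ~negative,          ~any_positive,
    "Treg",    c("CD3", "CD4", "CD25", "FOXP3"),       character(),        character(),
    "MAIT",    c("CD3", "Va72", "CD161"),              character(),        character(),
    "CD4T",    c("CD3", "CD4"),                        "CD8",              character(),
    "CD8T",    c("CD3", "CD8"),                        character(),        character(),
    "otherT",  "CD3",                                  character(),        character(),
    "NK",      "CD56",                                 "CD3",              character(),
    "B",       "CD19",                                 "CD3",              character(),
    "MonoDC",  character(),                            c("CD3", "CD19"),   c("CD14", "CD16", "CD11c")
  )
  if (!is.null(markers)) {
    # any-of sets keep their semantics when restricted to present markers
    # (rule dropped if none remain); required-positive/negative markers must
    # all exist for a rule to apply
    had_any <- lengths(rules$any_positive) > 0
    rules$any_positive <- map(rules$any_positive, intersect, markers)
    keep <- purrr::map_lgl(seq_len(nrow(rules)), function(i) {
      all(c(rules$positive[[i]], rules$negative[[i]]) %in% markers) &&
        !(had_any[i] && length(rules$any_positive[[i]]) == 0)
    })
    rules <- rules[keep, ]
  }
  rules
}

# Build a transformed-space (arcsinh) mean profile for a subset: `positive`
# markers sit high, everything else low.
subset_profile <- function(markers, positive, high = 3, low = 0.2) {
  setNames(ifelse(markers %in% positive, high, low), markers)
}

#' Construct a subset specification table
#'
#' One row per planted cell subset. `mean_profile` and `dispersion` are
#' per-marker vectors in transformed (arcsinh) space; `cohort_lfc` is a named
#' numeric of additive shifts on the logit-proportion scale (cohorts absent
#' from the vector get 0).
#'
#' @param subset_id,panel,lineage Character vectors (recycled row-wise).
#' @param mean_profile,dispersion,cohort_lfc List-columns (one entry per
#'   subset).
#' @param base_proportion Numeric; must sum to 1 within each panel.
#' @return A `subset_spec` tibble.
#' @export
subset_spec <- function(subset_id, panel, lineage, mean_profile,
                        dispersion, base_proportion, cohort_lfc) {
  out <- tibble(
    subset_id = subset_id, panel = panel, lineage = lineage,
    mean_profile = mean_profile, dispersion = dispersion,
    base_proportion = base_proportion, cohort_lfc = cohort_lfc
  )
  for (p in unique(out$panel)) {
    s <- sum(out$base_proportion[out$panel == p])
    if (abs(s - 1) > 1e-8) {
      abort(sprintf("base proportions for panel %s sum to %.6f, not 1", p, s))
    }
  }
  if (any(unlist(out$dispersion) <= 0)) {
    abort("dispersions must be strictly positive")
  }
  class(out) <- c("subset_spec", class(out))
  out
}

#' Default planted subsets for the two-panel simulation
#'
#' Sixteen T/NK subsets on panel P1 and fourteen B/myeloid subsets on panel
#' P2 — deliberately many, small subsets (base proportions 0.04-0.14), so
#' that the simplex closure of frequencies distorts the planted correlation
#' structure only mildly, as in real immunome data where each of ~80 nodes
#' is a small fraction of cells. Marker profiles are chosen so that the
#' default gating table recovers each subset's lineage from its scaled
#' median phenotype. Cohort shifts plant the case-control contrasts the
#' downstream stages must detect: cytotoxic/inflammatory NK subsets,
#' effector CD8 subsets, immature B cells and conventional dendritic cells
#' expand in heart failure (HF); an effector-memory CD4 subset and classical
#' monocytes contract; inflammatory MAIT, CD4 and Treg subsets are
#' additionally expanded in the preserved-ejection-fraction subgroup
#' (HFpEF) relative to the reduced-EF subgroup (HFrEF).
#'
#' @param panels Panel list as from [default_panels()].
#' @param dispersion Common per-marker dispersion in transformed space
#'   (default 0.35, i.e. separation/dispersion ratio 8 for the default
#'   high/low profile of 3/0.2).
#' @return A `subset_spec` tibble covering both panels.
#' @export
default_subsets <- function(panels = default_panels(), dispersion = 0.35) {
  m1 <- panels$P1$marker_names
  m2 <- panels$P2$marker_names
  p1 <- list(
    list("NK_rest",   "NK",     c("CD56"),                                    0.06, c()),
    list("NK_cyto",   "NK",     c("CD56", "GZMB", "CXCR3"),                   0.05, c(HF = 0.8)),
    list("NK_infl",   "NK",     c("CD56", "IL21", "GZMB", "IL10"),            0.04, c(HF = 0.8)),
    list("CD4_naive", "CD4T",   c("CD3", "CD4", "CD45RA", "CD28", "CCR7"),    0.10, c()),
    list("CD4_cm",    "CD4T",   c("CD3", "CD4", "CD45RO", "CCR7", "CD28"),    0.08, c()),
    list("CD4_em",    "CD4T",   c("CD3", "CD4", "CD45RO", "CD69", "CD28"),    0.07, c(HF = -0.4)),
    list("CD4_infl",  "CD4T",   c("CD3", "CD4", "CD45RO", "TNFa", "IFNg", "CD69"), 0.05, c(HFpEF = 0.7)),
    list("CD8_naive", "CD8T",   c("CD3", "CD8", "CD45RA", "CCR7"),            0.09, c()),
    list("CD8_em",    "CD8T",   c("CD3", "CD8", "CD45RO"),                    0.07, c(HF = -0.3)),
    list("CD8_eff",   "CD8T",   c("CD3", "CD8", "CD45RO", "GZMB", "TNFa", "IFNg"), 0.06, c(HF = 0.5)),
    list("CD8_lag",   "CD8T",   c("CD3", "CD8", "GZMB", "PD1"),               0.04, c(HF = 0.5)),
    list("MAIT_rest", "MAIT",   c("CD3", "Va72", "CD161", "CD8"),             0.05, c()),
    list("MAIT_infl", "MAIT",   c("CD3", "Va72", "CD161", "TNFa", "IFNg", "CD69", "CD45RO"), 0.04, c(HFpEF = 0.8)),
    list("Treg_rest", "Treg",   c("CD3", "CD4", "CD25", "FOXP3"),             0.05, c()),
    list("Treg_ccr6", "Treg",   c("CD3", "CD4", "CD25", "FOXP3", "CCR6"),     0.04, c(HFpEF = 0.4)),
    list("gdT_like",  "otherT", c("CD3", "CD161"),                            0.11, c())
  )
  p2 <- list(
    list("T_h",      "CD4T",   c("CD3", "CD4"),                               0.14, c()),
    list("T_c",      "CD8T",   c("CD3", "CD8"),                               0.12, c()),
    list("T_o",      "otherT", c("CD3"),                                      0.08, c()),
    list("NK_p2a",   "NK",     c("CD56"),                                     0.05, c()),
    list("NK_p2b",   "NK",     c("CD56", "CD16"),                             0.04, c(HF = 0.5)),
    list("B_naive",  "B",      c("CD19", "IgD", "IgM", "HLADR", "CXCR5"),     0.06, c(HF = 0.6)),
    list("B_mem",    "B",      c("CD19", "CD20", "CD24", "HLADR"),            0.06, c()),
    list("B_trans",  "B",      c("CD19", "CD24", "CD38", "IgM"),              0.04, c(HF = 0.4)),
    list("B_dn",     "B",      c("CD19", "HLADR", "CD38"),                    0.04, c()),
    list("mono_cl",  "MonoDC", c("CD14", "CCR2", "HLADR", "CD11b"),           0.14, c(HF = -0.5)),
    list("mono_int", "MonoDC", c("CD14", "CD16", "HLADR", "CCR2"),            0.06, c()),
    list("mono_nc",  "MonoDC", c("CD16", "HLADR", "CD11b"),                   0.05, c()),
    list("cDC",      "MonoDC", c("CD16", "CD11c", "IFNg", "CD38", "IL1b", "HLADR"), 0.05, c(HF = 0.7)),
    list("DC_o",     "MonoDC", c("CD11c", "HLADR", "CD31"),                   0.07, c())
  )
  build <- function(rows, panel, markers) {
    subset_spec(
      subset_id = map_chr(rows, 1),
      panel = panel,
      lineage = map_chr(rows, 2),
      mean_profile = map(rows, ~ subset_profile(markers, .x[[3]])),
      dispersion = map(rows, ~ setNames(rep(dispersion, length(markers)), markers)),
      base_proportion = map_dbl(rows, 4),
      cohort_lfc = map(rows, 5)
    )
  }
  out <- bind_rows(build(p1, "P1", m1), build(p2, "P2", m2))
  class(out) <- c("subset_spec", class(out))
  out
}
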