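#' Relative ionic mobility table
#'
#' Relative mobilities u (dimensionless, K+ = 1) used by the Henderson
#' junction-potential calculation. Values are derived from limiting molar
#' conductivities at 25 C as u = lambda_molar / (z^2 * lambda_K), the
#' weighting under which `z^2 * u * c` is proportional to the ionic
#' conductivity contribution: K 73.5, Na 50.1, Cs 77.3, Li 38.7,
#' TEA 32.7, NH4 73.6, Ca 119, Mg 106, Ba 127.3 (molar), Cl 76.4, Br 78.1,
#' HCO3 44.5, H2PO4 33, NO3 71.5, SO4 160 (molar), acetate 40.9,
#' methanesulfonate 48.8, gluconate 24.3, HEPES 22, EGTA(2-) 70.6 (molar).
#' Organic species with no tabulated conductivity (4-aminopyridinium,
#' kynurenate) carry documented estimates in the class of similarly sized
#' organic ions. Temperature dependence of the ratios is neglected.
#'
#' @return A tibble with columns `ion`, `charge`, `mobility`.
#' @export
ion_mobility_table <- function() {
  tribble(
    ~ion,               ~charge, ~mobility,
    "K",                 1L, 1.0000,
    "Na",                1L, 0.6816,
    "Li",                1L, 0.5265,
    "Cs",                1L, 1.0517,
    "NH4",               1L, 1.0014,
    "TEA",               1L, 0.4449,
    "TMA",               1L, 0.6109,
    "4AP",               1L, 0.4550,  # estimate: aromatic amine cation
    "H",                 1L, 4.7619,
    "Ca",                2L, 0.4048,
    "Mg",                2L, 0.3605,
    "Ba",                2L, 0.4330,
    "Cl",               -1L, 1.0395,
    "Br",               -1L, 1.0626,
    "F",                -1L, 0.7537,
    "NO3",              -1L, 0.9721,
    "HCO3",             -1L, 0.6054,
    "H2PO4",            -1L, 0.4490,
    "SO4",              -2L, 0.5442,
    "acetate",          -1L, 0.5565,
    "methanesulfonate", -1L, 0.6639,
    "gluconate",        -1L, 0.3306,
    "HEPES",            -1L, 0.2993,
    "MES",              -1L, 0.3700,
    "EGTA",             -2L, 0.2401,
    "kynurenate",       -1L, 0.3000   # estimate: large aromatic anion
  )
}

#' Define a solution composition
#'
#' Builds a `solution` (tibble of dissolved species) from named
#' concentrations in mM, expanding common electrophysiology salts and
#' buffers into their constituent ions. Recognized compound names include
#' `KCl`, `NaCl`, `CsCl`, `"K-gluconate"`, `"Cs-methanesulfonate"`,
#' `"TEA-Cl"`, `MgCl2`, `CaCl2`, `NaHCO3`, `NaH2PO4`, `HEPES`, `EGTA`,
#' `"4-AP"`, `"kynurenic acid"`, and neutral or chelated species that are
#' excluded from junction calculations (`glucose`, `sucrose`, `mannitol`,
#' `picrotoxin`, `MgATP`, `NaGTP`). Weak acids carry a fixed fractional
#' charge at pH 7.2: HEPES contributes 0.334 of its concentration as the
#' monoanion (pKa 7.5); EGTA is taken as the divalent anion. Compositions
#' are entered exactly as printed in a Methods table; the titration base is
#' not added.
#'
#' @param ... Named concentrations in mM, e.g. `solution(KCl = 2.5, NaCl = 126)`.
#' @param pH Solution pH (recorded; fractional charges are fixed at their
#'   pH 7.2 values).
#' @return A tibble with columns `ion`, `charge`, `mM` and attribute `pH`;
#'   class `solution`.
#' @examples
#' solution(`K-gluconate` = 120, KCl = 11, HEPES = 10, MgCl2 = 1,
#'          CaCl2 = 1, EGTA = 11, MgATP = 4, NaGTP = 0.5)
#' @export
solution <- function(..., pH = 7.2) {
  conc <- c(...)
  if (is.null(names(conc)) || any(!nzchar(names(conc))))
    abort("all concentrations must be named, e.g. solution(KCl = 2.5).")
  if (any(conc < 0)) abort("concentrations must be >= 0 mM.")
  parts <- purrr::imap(conc, expand_species) %>% list_rbind()
  parts <- parts %>%
    group_by(.data$ion, .data$charge) %>%
    summarise(mM = sum(.data$mM), .groups = "drop")
  ions <- filter(parts, .data$charge != 0, .data$mM > 0)
  if (!any(ions$charge > 0) || !any(ions$charge < 0))
    abort("a solution must contain at least one cation and one anion.")
  structure(parts, class = c("solution", class(parts)), pH = pH)
}

# fraction of HEPES present as the monoanion at pH 7.2 (pKa 7.5)
HEPES_ANION_FRACTION <- 1 / (1 + 10^(7.5 - 7.2))

expand_species <- function(mM, name) {
  key <- gsub("[-_ ]", "", tolower(name))
  sp <- function(...) {
    d <- tribble(~ion, ~charge, ~frac, ...)
    tibble(ion = d$ion, charge = as.integer(d$charge), mM = mM * d$frac)
  }
  switch(key,
    "kcl" = sp("K", 1, 1, "Cl", -1, 1),
    "nacl" = sp("Na", 1, 1, "Cl", -1, 1),
    "cscl" = sp("Cs", 1, 1, "Cl", -1, 1),
    "licl" = sp("Li", 1, 1, "Cl", -1, 1),
    "kgluconate" = sp("K", 1, 1, "gluconate", -1, 1),
    "csmethanesulfonate" = , "csmesulf" = ,
    "csms" = sp("Cs", 1, 1, "methanesulfonate", -1, 1),
    "kmethanesulfonate" = sp("K", 1, 1, "methanesulfonate", -1, 1),
    "teacl" = , "tetraethylammonium-cl" = ,
    "tetraethylammoniumcl" = sp("TEA", 1, 1, "Cl", -1, 1),
    "mgcl2" = sp("Mg", 2, 1, "Cl", -1, 2),
    "cacl2" = sp("Ca", 2, 1, "Cl", -1, 2),
    "bacl2" = sp("Ba", 2, 1, "Cl", -1, 2),
    "nahco3" = sp("Na", 1, 1, "HCO3", -1, 1),
    "nah2po4" = sp("Na", 1, 1, "H2PO4", -1, 1),
    "khco3" = sp("K", 1, 1, "HCO3", -1, 1),
    "na2so4" = sp("Na", 1, 2, "SO4", -2, 1),
    "hepes" = sp("HEPES", -1, HEPES_ANION_FRACTION),
    "egta" = sp("EGTA", -2, 1),
    "4ap" = , "4aminopyridine" = sp("4AP", 1, 1),
    "kynurenicacid" = , "kynurenate" = sp("kynurenate", -1, 1),
    # neutral / chelated species: excluded from junction computation
    "glucose" = , "sucrose" = , "mannitol" = , "dmannitol" = ,
    "picrotoxin" = , "mgatp" = , "nagtp" = , "natp" = ,
    "atp" = , "gtp" = tibble(ion = name, charge = 0L, mM = mM),
    # fall through: a bare ion name resolvable in the mobility table
    {
      tab <- ion_mobility_table()
      hit <- match(name, tab$ion)
      if (is.na(hit))
        abort(sprintf("unknown species '%s'; add it to the mobility table or enter its ions directly.", name))
      tibble(ion = name, charge = tab$charge[hit], mM = mM)
    })
}

#' Generalized Henderson liquid junction potential
#'
#' Computes the junction potential between the pipette and bath solutions
#' with the generalized Henderson equation,
#' \deqn{V = \frac{RT}{F}\,
#'   \frac{\sum_i z_i u_i \Delta c_i}{\sum_i z_i^2 u_i \Delta c_i}\,
#'   \ln\frac{\sum_i z_i^2 u_i c_i^{pip}}{\sum_i z_i^2 u_i c_i^{bath}}}
#' with \eqn{\Delta c_i = c_i^{pip} - c_i^{bath}}, relative mobilities
#' \eqn{u_i} from [ion_mobility_table()], and the pipette-minus-bath sign
#' convention under which a K-gluconate pipette in a NaCl bath yields a
#' positive value. The returned value is the amount to subtract from
#' measured potentials ([apply_junction_correction()]).
#'
#' Charged species missing from the mobility table raise an error when
#' present above `drop_limit_mM` unless whitelisted via `drop`; neutral
#' species are always excluded and reported in the species audit.
#'
#' @param pipette,bath [solution()] objects.
#' @param table Mobility table (defaults to [ion_mobility_table()]).
#' @param temperature_K Junction temperature; default 307 K (34 C bath).
#' @param drop Character vector of charged species to drop silently.
#' @param drop_limit_mM Concentration above which an unresolvable charged
#'   species is an error rather than a warning.
#' @return An `ljp_result` list: `ljp_mV`, `temperature_K`, `species_used`,
#'   `species_dropped`.
#' @examples
#' pip <- solution(`K-gluconate` = 120, KCl = 11, HEPES = 10, MgCl2 = 1,
#'                 CaCl2 = 1, EGTA = 11, MgATP = 4, NaGTP = 0.5)
#' bath <- solution(NaCl = 126, KCl = 2.5, NaHCO3 = 26, NaH2PO4 = 1.25,
#'                  CaCl2 = 2, MgCl2 = 2, glucose = 10,
#'                  `kynurenic acid` = 1, picrotoxin = 0.1)
#' henderson_ljp(pip, bath)
#' @export
henderson_ljp <- function(pipette, bath, table = ion_mobility_table(),
                          temperature_K = 307, drop = character(),
                          drop_limit_mM = 1) {
  stopifnot(inherits(pipette, "solution"), inherits(bath, "solution"))
  both <- dplyr::full_join(
    select(as_tibble(pipette), "ion", "charge", pip = "mM"),
    select(as_tibble(bath), "ion", "charge", bath = "mM"),
    by = c("ion", "charge")) %>%
    mutate(pip = ifelse(is.na(.data$pip), 0, .data$pip),
           bath = ifelse(is.na(.data$bath), 0, .data$bath))
  neutral <- filter(both, .data$charge == 0L)
  charged <- filter(both, .data$charge != 0L) %>%
    dplyr::left_join(select(table, "ion", "mobility"), by = "ion")
  unresolved <- filter(charged, is.na(.data$mobility), !.data$ion %in% drop)
  over <- filter(unresolved, pmax(.data$pip, .data$bath) > drop_limit_mM)
  if (nrow(over))
    abort(sprintf("charged species with no mobility entry above %g mM: %s.",
                  drop_limit_mM, paste(over$ion, collapse = ", ")))
  used <- filter(charged, !is.na(.data$mobility))
  dropped <- c(neutral$ion, filter(charged, is.na(.data$mobility))$ion)

  z <- used$charge; u <- used$mobility
  d <- used$pip - used$bath
  s_pip <- sum(z^2 * u * used$pip)
  s_bath <- sum(z^2 * u * used$bath)
  den <- sum(z^2 * u * d)
  rtf <- 8.31446 * temperature_K / 96485.332 * 1000 # mV
  ljp <- if (abs(s_pip - s_bath) < 1e-12 * max(s_pip, s_bath)) {
    0
  } else {
    if (abs(den) < 1e-9 * max(s_pip, s_bath))
      abort("Henderson denominator is ~0 for these solutions; the equation is singular.")
    rtf * sum(z * u * d) / den * log(s_pip / s_bath)
  }
  structure(list(ljp_mV = ljp, temperature_K = temperature_K,
                 species_used = used$ion, species_dropped = unique(dropped)),
            class = "ljp_result")
}

#' @export
print.ljp_result <- function(x, ...) {
  cat(sprintf("Henderson liquid junction potential: %+.2f mV at %g K\n",
              x$ljp_mV, x$temperature_K))
  cat("  species used:   ", paste(x$species_used, collapse = ", "), "\n")
  if (length(x$species_dropped))
    cat("  species dropped:", paste(x$species_dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Recording solutions used by the standard thalamic slice protocols
#'
#' The four compositions (mM) from the slice recording methods: the
#' K-gluconate current-clamp pipette solution, the NaCl-based current-clamp
#' bath, the Cs-methanesulfonate voltage-clamp pipette solution, and the
#' TEA-Cl voltage-clamp bath.
#'
#' @param name One of `"cc_pipette"`, `"cc_bath"`, `"vc_pipette"`, `"vc_bath"`.
#' @return A [solution()].
#' @export
solution_preset <- function(name = c("cc_pipette", "cc_bath",
                                     "vc_pipette", "vc_bath")) {
  name <- match.arg(name)
  switch(name,
    cc_pipette = solution(`K-gluconate` = 120, HEPES = 10, MgCl2 = 1,
                          CaCl2 = 1, KCl = 11, EGTA = 11, MgATP = 4,
                          NaGTP = 0.5),
    cc_bath = solution(NaCl = 126, KCl = 2.5, NaHCO3 = 26, NaH2PO4 = 1.25,
                       CaCl2 = 2, MgCl2 = 2, glucose = 10,
                       `kynurenic acid` = 1, picrotoxin = 0.1),
    vc_pipette = solution(`Cs-methanesulfonate` = 120, HEPES = 10,
                          MgCl2 = 0.5, CaCl2 = 1, `TEA-Cl` = 10,
                          `4-AP` = 5, EGTA = 11, MgATP = 4, NaGTP = 0.5),
    vc_bath = solution(`TEA-Cl` = 126, KCl = 2.5, NaHCO3 = 26,
                       NaH2PO4 = 1.25, CaCl2 = 2, MgCl2 = 2, glucose = 10,
                       `kynurenic acid` = 1, picrotoxin = 0.1))
}
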