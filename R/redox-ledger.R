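## Stoichiometric ledger of the hydrogen economy of catechin and
## phloroglucinol degradation.
##
## All arithmetic on stoichiometric coefficients is exact rational
## (integer numerator/denominator pairs); no floating point enters the
## balance or the H2 bookkeeping.

## ---- exact rational helpers ------------------------------------------------

rat_gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}

## a rational is c(n = numerator, d = denominator), d > 0, reduced
rat <- function(n, d = 1) {
  n <- unname(n); d <- unname(d)
  if (d == 0) stop("zero denominator")
  if (n != round(n) || d != round(d)) stop("rational parts must be integers")
  if (d < 0) { n <- -n; d <- -d }
  g <- rat_gcd(n, d); if (g == 0) g <- 1
  c(n = n / g, d = d / g)
}

rat_add <- function(x, y) rat(x["n"] * y["d"] + y["n"] * x["d"], x["d"] * y["d"])
rat_mul <- function(x, y) rat(x["n"] * y["n"], x["d"] * y["d"])
rat_neg <- function(x) rat(-x["n"], x["d"])
rat_is0 <- function(x) x["n"] == 0
rat_num <- function(x) unname(x["n"] / x["d"])

## parse an integer, integer-valued numeric, or "a/b" string
as_rat <- function(x) {
  if (is.character(x)) {
    parts <- strsplit(x, "/", fixed = TRUE)[[1]]
    if (length(parts) == 1) return(rat(as.numeric(parts)))
    return(rat(as.numeric(parts[1]), as.numeric(parts[2])))
  }
  if (x != round(x))
    stop("non-integer coefficient; supply exact fractions as \"a/b\"")
  rat(x)
}

## ---- chemical species ------------------------------------------------------

#' Parse a molecular formula string
#'
#' Accepts compact (`"C6H5Cl"`) or spaced (`"C6 H5 Cl"`) element
#' notation with optional counts.
#'
#' @param formula Formula string.
#' @return Named integer vector of element counts, or `NULL` if the
#'   string cannot be parsed.
#' @export
parse_formula <- function(formula) {
  if (is.na(formula) || !nzchar(trimws(formula))) return(NULL)
  s <- gsub("[[:space:]]", "", formula)
  m <- gregexpr("[A-Z][a-z]?[0-9]*", s)[[1]]
  toks <- regmatches(s, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(s)) return(NULL)
  el <- sub("[0-9]*$", "", toks)
  ct <- as.integer(sub("^[A-Za-z]+", "", toks))
  ct[is.na(ct)] <- 1L
  counts <- tapply(ct, el, sum)
  stats::setNames(as.integer(counts), names(counts))
}

#' Define a chemical species for the redox ledger
#'
#' @param name Species name (the key used in reactions).
#' @param formula Formula string (may be `""` for electron-carrier
#'   bookkeeping species such as the ferredoxin couple).
#' @param charge Integer net charge.
#' @param role One of `"metabolite"`, `"cofactor"`, `"gas"`, `"water"`,
#'   `"proton"`.
#' @return List of class `chem_species`.
#' @export
chem_species <- function(name, formula, charge = 0L,
                         role = c("metabolite", "cofactor", "gas",
                                  "water", "proton")) {
  role <- match.arg(role)
  counts <- if (nzchar(formula)) parse_formula(formula) else
    stats::setNames(integer(0), character(0))
  if (nzchar(formula) && is.null(counts))
    stop("unparseable formula for ", name, ": ", formula)
  if (any(counts < 0)) stop("negative element count in ", name)
  structure(list(name = name, formula = counts, charge = as.integer(charge),
                 role = role), class = "chem_species")
}

## degree of reduction (available electrons) of one species:
## sum of element valences minus net charge
species_electrons <- function(sp) {
  val <- c(C = 4, H = 1, O = -2, N = -3, S = 6, P = 5)
  f <- sp$formula
  unknown <- setdiff(names(f), names(val))
  if (length(unknown) > 0)
    stop("no valence convention for element(s): ",
         paste(unknown, collapse = ", "))
  sum(val[names(f)] * f) - sp$charge
}

#' The shipped species library
#'
#' Flavonoids and phenolic intermediates of anaerobic catechin
#' degradation, fermentation end products, gases, and the cofactor
#' couples. Cofactor couples use minimal bookkeeping formulas that
#' differ by exactly the transferred hydrogen/charge (NAD(P)+/NAD(P)H
#' as a 2-electron/1-H couple; ferredoxin as an atom-free 2-electron
#' couple), which keeps every redox reaction exactly element- and
#' charge-balanceable.
#'
#' @return Named list of [chem_species()].
#' @export
ledger_species <- function() {
  sp <- list(
    chem_species("catechin",               "C15H14O6"),
    chem_species("taxifolin",              "C15H12O7"),
    chem_species("eriodictyol",            "C15H12O6"),
    chem_species("naringenin",             "C15H12O5"),
    chem_species("dihydrokaempferol",      "C15H12O6"),
    chem_species("alphitonin",             "C15H12O7"),
    chem_species("maesopsin",              "C15H12O6"),
    chem_species("phloretin",              "C15H14O5"),
    chem_species("taxifolin_dihydrochalcone",   "C15H14O7"),
    chem_species("eriodictyol_dihydrochalcone", "C15H14O6"),
    chem_species("phloroglucinol",         "C6H6O3"),
    chem_species("dihydrophloroglucinol",  "C6H8O3"),
    chem_species("pyrogallol",             "C6H6O3"),
    chem_species("dihydroxyphenyllactate",    "C9H10O5"),
    chem_species("dihydroxyphenylpropionate", "C9H10O4"),
    chem_species("hydroxyphenylpropionate",   "C9H10O3"),
    chem_species("dihydroxyphenylacetate",    "C8H8O4"),
    chem_species("hydroxyphenylacetate",      "C8H8O3"),
    chem_species("acetate",  "C2H4O2"),
    chem_species("butyrate", "C4H8O2"),
    chem_species("formate",  "CH2O2"),
    chem_species("CO2", "CO2", role = "gas"),
    chem_species("CH4", "CH4", role = "gas"),
    chem_species("H2",  "H2",  role = "gas"),
    chem_species("H2O", "H2O", role = "water"),
    chem_species("H+",  "H", charge = 1L, role = "proton"),
    chem_species("NAD+",  "", charge = 1L, role = "cofactor"),
    chem_species("NADH",  "H", role = "cofactor"),
    chem_species("NADP+", "", charge = 1L, role = "cofactor"),
    chem_species("NADPH", "H", role = "cofactor"),
    chem_species("Fdox",  "", role = "cofactor"),
    chem_species("Fdred", "", charge = -2L, role = "cofactor"))
  stats::setNames(sp, vapply(sp, `[[`, "", "name"))
}

#' Cofactor couples tracked by the ledger
#'
#' Each couple lists its oxidized and reduced member. The ferredoxin
#' couple carries two electrons per unit, which makes the Rnf reaction
#' (Fdred + NAD+ -> Fdox + NADH) electron-neutral as written.
#'
#' @return Named list of `c(ox=, red=)` pairs.
#' @export
ledger_couples <- function() {
  list(nad  = c(ox = "NAD+",  red = "NADH"),
       nadp = c(ox = "NADP+", red = "NADPH"),
       fd   = c(ox = "Fdox",  red = "Fdred"))
}

## ---- reactions -------------------------------------------------------------

#' Define a reaction
#'
#' @param reaction_id Identifier.
#' @param stoich Named vector/list of signed coefficients (negative =
#'   consumed). Integer-valued numerics or `"a/b"` fraction strings.
#' @param enzyme Enzyme label (free text).
#' @param reversible Logical.
#' @return List of class `ledger_reaction`; coefficients stored as
#'   exact rationals.
#' @export
reaction <- function(reaction_id, stoich, enzyme = "", reversible = FALSE) {
  if (is.null(names(stoich)) || any(!nzchar(names(stoich))))
    stop("stoich must be fully named by species")
  coeffs <- lapply(stoich, as_rat)
  structure(list(reaction_id = reaction_id, stoich = coeffs,
                 enzyme = enzyme, reversible = reversible),
            class = "ledger_reaction")
}

#' Check element and charge balance of a reaction
#'
#' @param r A [reaction()].
#' @param species Species library (default [ledger_species()]).
#' @return List with `balanced` (logical), `element_residuals` (named
#'   numeric; substrate-side minus product-side atom counts, so a
#'   negative value means the substrates are short of that element)
#'   and `charge_residual` (same convention).
#' @export
check_balance <- function(r, species = ledger_species()) {
  unknown <- setdiff(names(r$stoich), names(species))
  if (length(unknown) > 0)
    stop("unknown species in ", r$reaction_id, ": ",
         paste(unknown, collapse = ", "))
  elem <- numeric(0); charge <- 0
  for (nm in names(r$stoich)) {
    cf <- -rat_num(r$stoich[[nm]])  # substrates (cf < 0) count positive
    sp <- species[[nm]]
    for (el in names(sp$formula)) {
      if (!el %in% names(elem)) elem[el] <- 0
      elem[el] <- elem[el] + cf * sp$formula[[el]]
    }
    charge <- charge + cf * sp$charge
  }
  list(balanced = all(elem == 0) && charge == 0,
       element_residuals = elem, charge_residual = charge)
}

#' The shipped reaction library
#'
#' Balanced reactions of the anaerobic catechin, phloroglucinol, and
#' reference methanogenesis chemistry, plus the four electron-recycling
#' systems. Dehydroxylations are written as NADH-dependent 2-electron
#' reductions releasing water; FCR and PGR as NADPH-dependent
#' 2-electron reductions; CHI isomerizations and hydrolytic cleavages
#' are redox-neutral. Because recycling closes every couple from H2,
#' the final H2 arithmetic is independent of which couple any
#' individual reductive step is assigned to.
#'
#' @return Named list of [reaction()]s.
#' @export
ledger_reactions <- function() {
  rx <- list(
    ## C-ring / B-ring dehydroxylations (2-electron reductions)
    reaction("tax_to_eri",
             c(taxifolin = -1, NADH = -1, `H+` = -1,
               eriodictyol = 1, `NAD+` = 1, H2O = 1), enzyme = "CDH"),
    reaction("eri_to_nar",
             c(eriodictyol = -1, NADH = -1, `H+` = -1,
               naringenin = 1, `NAD+` = 1, H2O = 1), enzyme = "CDH"),
    reaction("tax_to_dhk",
             c(taxifolin = -1, NADH = -1, `H+` = -1,
               dihydrokaempferol = 1, `NAD+` = 1, H2O = 1), enzyme = "CDH"),
    ## FCR: C-ring reductive opening to the dihydrochalcone
    reaction("fcr_taxifolin",
             c(taxifolin = -1, NADPH = -1, `H+` = -1,
               taxifolin_dihydrochalcone = 1, `NADP+` = 1), enzyme = "FCR"),
    reaction("fcr_eriodictyol",
             c(eriodictyol = -1, NADPH = -1, `H+` = -1,
               eriodictyol_dihydrochalcone = 1, `NADP+` = 1), enzyme = "FCR"),
    reaction("fcr_naringenin",
             c(naringenin = -1, NADPH = -1, `H+` = -1,
               phloretin = 1, `NADP+` = 1), enzyme = "FCR"),
    ## PHY: hydrolytic cleavage of dihydrochalcones
    reaction("phy_taxifolin_dhc",
             c(taxifolin_dihydrochalcone = -1, H2O = -1,
               phloroglucinol = 1, dihydroxyphenyllactate = 1),
             enzyme = "PHY"),
    reaction("phy_eriodictyol_dhc",
             c(eriodictyol_dihydrochalcone = -1, H2O = -1,
               phloroglucinol = 1, dihydroxyphenylpropionate = 1),
             enzyme = "PHY"),
    reaction("phy_phloretin",
             c(phloretin = -1, H2O = -1,
               phloroglucinol = 1, hydroxyphenylpropionate = 1),
             enzyme = "PHY"),
    ## CHI ring contractions (redox-neutral isomerizations)
    reaction("chi_taxifolin",
             c(taxifolin = -1, alphitonin = 1), enzyme = "CHI"),
    reaction("chi_dihydrokaempferol",
             c(dihydrokaempferol = -1, maesopsin = 1), enzyme = "CHI"),
    ## auronol cleavage: C6 + C8 products plus one C1 unit (formate)
    reaction("cleave_alphitonin",
             c(alphitonin = -1, H2O = -2,
               phloroglucinol = 1, dihydroxyphenylacetate = 1, formate = 1),
             enzyme = "auronol hydrolase (uncharacterized)"),
    reaction("cleave_maesopsin",
             c(maesopsin = -1, H2O = -2,
               phloroglucinol = 1, hydroxyphenylacetate = 1, formate = 1),
             enzyme = "auronol hydrolase (uncharacterized)"),
    ## phloroglucinol shunt
    reaction("pgr",
             c(phloroglucinol = -1, NADPH = -1, `H+` = -1,
               dihydrophloroglucinol = 1, `NADP+` = 1), enzyme = "PGR"),
    reaction("dhpg_to_acetate",
             c(dihydrophloroglucinol = -1, H2O = -3, `NAD+` = -1,
               acetate = 3, NADH = 1, `H+` = 1),
             enzyme = "ring hydrolysis + beta-oxidative cleavage"),
    reaction("pgth",
             c(pyrogallol = -1, phloroglucinol = 1),
             enzyme = "pgthAB", reversible = TRUE),
    ## hydrogenotrophic methanogenesis reference
    reaction("methanogenesis_reference",
             c(CO2 = -1, H2 = -4, CH4 = 1, H2O = 2),
             enzyme = "Mcr-reference"),
    ## electron-recycling systems
    reaction("pntab",
             c(NADH = -1, `NADP+` = -1, `NAD+` = 1, NADPH = 1),
             enzyme = "PntAB", reversible = TRUE),
    reaction("rnf",
             c(Fdred = -1, `NAD+` = -1, `H+` = -1, Fdox = 1, NADH = 1),
             enzyme = "Rnf", reversible = TRUE),
    reaction("fefe_a3",
             c(H2 = -2, `NAD+` = -1, Fdox = -1,
               NADH = 1, Fdred = 1, `H+` = 3),
             enzyme = "FeFe-A3", reversible = TRUE),
    reaction("nife_4e",
             c(Fdred = -1, `H+` = -2, Fdox = 1, H2 = 1),
             enzyme = "NiFe-4e", reversible = TRUE))
  stats::setNames(rx, vapply(rx, `[[`, "", "reaction_id"))
}

## ---- routes ----------------------------------------------------------------

#' Define a degradation route
#'
#' @param route_id Identifier.
#' @param reaction_ids Ordered reaction ids (with multiplicity: repeat
#'   an id to apply a reaction more than once).
#' @param substrate Substrate species name.
#' @param terminal Character vector of terminal product species.
#' @return List of class `ledger_route`.
#' @export
route <- function(route_id, reaction_ids, substrate, terminal) {
  structure(list(route_id = route_id, reaction_ids = reaction_ids,
                 substrate = substrate, terminal = terminal),
            class = "ledger_route")
}

#' The shipped route library
#'
#' The three metabolite-inferred taxifolin degradation routes (via
#' naringenin, eriodictyol, and dihydrokaempferol), the two previously
#' characterized routes (direct FCR cleavage of taxifolin, and CHI
#' ring-contraction to alphitonin), and the hydrogenotrophic
#' methanogenesis reference reaction. Catechin routes include the
#' downstream degradation of their phloroglucinol product by default;
#' the upstream catechin-to-taxifolin activation (uncharacterized
#' enzymes, external oxidant) is outside the ledger, and all routes are
#' reported per mole catechin via the 1:1 catechin:taxifolin
#' stoichiometry.
#'
#' @param include_phloroglucinol Append the phloroglucinol degradation
#'   steps to each catechin route (default TRUE).
#' @return Named list of [route()]s.
#' @export
ledger_routes <- function(include_phloroglucinol = TRUE) {
  pg <- if (include_phloroglucinol) c("pgr", "dhpg_to_acetate") else character(0)
  pg_terminal <- if (include_phloroglucinol) "acetate" else "phloroglucinol"
  rt <- list(
    route("naringenin",
          c("tax_to_eri", "eri_to_nar", "fcr_naringenin",
            "phy_phloretin", pg),
          substrate = "taxifolin",
          terminal = c("hydroxyphenylpropionate", pg_terminal)),
    route("eriodictyol",
          c("tax_to_eri", "fcr_eriodictyol", "phy_eriodictyol_dhc", pg),
          substrate = "taxifolin",
          terminal = c("dihydroxyphenylpropionate", pg_terminal)),
    route("dihydrokaempferol",
          c("tax_to_dhk", "chi_dihydrokaempferol", "cleave_maesopsin", pg),
          substrate = "taxifolin",
          terminal = c("hydroxyphenylacetate", "formate", pg_terminal)),
    route("taxifolin_fcr",
          c("fcr_taxifolin", "phy_taxifolin_dhc", pg),
          substrate = "taxifolin",
          terminal = c("dihydroxyphenyllactate", pg_terminal)),
    route("alphitonin",
          c("chi_taxifolin", "cleave_alphitonin", pg),
          substrate = "taxifolin",
          terminal = c("dihydroxyphenylacetate", "formate", pg_terminal)),
    route("methanogenesis_reference",
          "methanogenesis_reference",
          substrate = "CO2", terminal = "CH4"))
  stats::setNames(rt, vapply(rt, `[[`, "", "route_id"))
}

## sum stoichiometries (rational) of a list of reactions
sum_stoich <- function(reactions) {
  acc <- list()
  for (r in reactions) {
    for (nm in names(r$stoich)) {
      acc[[nm]] <- if (is.null(acc[[nm]])) r$stoich[[nm]]
                   else rat_add(acc[[nm]], r$stoich[[nm]])
    }
  }
  acc[!vapply(acc, rat_is0, logical(1))]
}

#' Net reaction of a route
#'
#' Sums the route's reactions coefficient-wise. Metabolite
#' intermediates (everything with role `"metabolite"` other than the
#' substrate and declared terminal products) must cancel exactly.
#'
#' @param rt A [route()].
#' @param reactions Reaction library (default [ledger_reactions()]).
#' @param species Species library.
#' @return A [reaction()] holding the net stoichiometry.
#' @export
net_reaction <- function(rt, reactions = ledger_reactions(),
                         species = ledger_species()) {
  missing <- setdiff(rt$reaction_ids, names(reactions))
  if (length(missing) > 0)
    stop("route ", rt$route_id, " references unknown reactions: ",
         paste(missing, collapse = ", "))
  for (id in unique(rt$reaction_ids)) {
    b <- check_balance(reactions[[id]], species)
    if (!b$balanced) stop("reaction ", id, " is not balanced")
  }
  net <- sum_stoich(reactions[rt$reaction_ids])
  roles <- vapply(species[names(net)], `[[`, "", "role")
  leftover <- setdiff(names(net)[roles == "metabolite"],
                      c(rt$substrate, rt$terminal))
  if (length(leftover) > 0)
    stop("non-cancelling intermediate(s) in route ", rt$route_id, ": ",
         paste(leftover, collapse = ", "))
  out <- structure(list(reaction_id = paste0("net_", rt$route_id),
                        stoich = net, enzyme = "net", reversible = FALSE),
                   class = "ledger_reaction")
  b <- check_balance(out, species)
  if (!b$balanced) stop("net reaction of ", rt$route_id, " is not balanced")
  out
}

## ---- recycling and the H2 balance -----------------------------------------

#' The default recycling cascade
#'
#' Ordered electron-recycling systems with the couple member each one
#' is used to drive to zero: the NAD(P) transhydrogenase (PntAB,
#' targets NADPH), the Rnf complex (ferredoxin:NAD+ oxidoreductase,
#' targets reduced ferredoxin), the electron-bifurcating [FeFe]-A3
#' hydrogenase (2 H2 + NAD+ + Fdox -> NADH + Fdred; targets NADH), and
#' the ferredoxin-oxidizing, H2-evolving [NiFe]-4e hydrogenase
#' (targets reduced ferredoxin).
#'
#' @return List of `list(reaction_id, target)` entries.
#' @export
recycling_systems <- function() {
  list(list(reaction_id = "pntab",   target = "NADPH"),
       list(reaction_id = "rnf",     target = "Fdred"),
       list(reaction_id = "fefe_a3", target = "NADH"),
       list(reaction_id = "nife_4e", target = "Fdred"))
}

rat_get <- function(stoich, nm) if (is.null(stoich[[nm]])) rat(0) else stoich[[nm]]

#' Close the cofactor couples of a net reaction and tally H2
#'
#' Applies the recycling systems, each the exact number of times that
#' drives its target species to zero (iterating over the cascade until
#' no further progress), then verifies every cofactor couple is closed.
#' The H2 ledger separates gross H2 consumed (explicit route H2 plus
#' bifurcating-hydrogenase input) from gross H2 evolved (explicit plus
#' [NiFe]-4e output).
#'
#' @param net A net [reaction()] (see [net_reaction()]).
#' @param systems Recycling cascade (default [recycling_systems()]).
#' @param reactions Reaction library.
#' @param species Species library.
#' @param strict_integral Require integral system multiplicities
#'   (default TRUE).
#' @return List of class `h2_balance`: `h2_consumed`, `h2_produced`
#'   (net, each floored at zero), `gross_h2_in`, `gross_h2_out`,
#'   `systems_used` (named multiplicities), `closed_stoich` (the net
#'   stoichiometry after recycling, numeric).
#' @export
apply_recycling <- function(net, systems = recycling_systems(),
                            reactions = ledger_reactions(),
                            species = ledger_species(),
                            strict_integral = TRUE) {
  b <- check_balance(net, species)
  if (!b$balanced) stop("net reaction must be balanced before recycling")
  couples <- ledger_couples()
  cur <- net$stoich
  used <- stats::setNames(rep(0, length(systems)),
                          vapply(systems, `[[`, "", "reaction_id"))
  passes <- 0
  repeat {
    passes <- passes + 1
    if (passes > 100)
      stop("cofactor couples not closable with the given systems ",
           "(cascade did not converge under this ordering)")
    progress <- FALSE
    for (sys in systems) {
      rxn <- reactions[[sys$reaction_id]]
      if (is.null(rxn)) stop("unknown recycling system: ", sys$reaction_id)
      tgt <- rat_get(cur, sys$target)
      if (rat_is0(tgt)) next
      scf <- rat_get(rxn$stoich, sys$target)
      if (rat_is0(scf))
        stop("system ", sys$reaction_id, " does not act on ", sys$target)
      mult <- rat_mul(rat_neg(tgt), rat(scf[["d"]], scf[["n"]]))
      if (mult[["n"]] < 0 && !rxn$reversible) next
      if (strict_integral && mult[["d"]] != 1)
        stop("couples not closable with integral uses of ",
             sys$reaction_id, " (needs ", mult[["n"]], "/", mult[["d"]],
             " applications)")
      for (nm in names(rxn$stoich))
        cur[[nm]] <- rat_add(rat_get(cur, nm),
                             rat_mul(mult, rxn$stoich[[nm]]))
      used[sys$reaction_id] <- used[sys$reaction_id] + rat_num(mult)
      progress <- TRUE
    }
    open <- vapply(couples, function(cp)
      !rat_is0(rat_get(cur, cp[["red"]])) ||
      !rat_is0(rat_get(cur, cp[["ox"]])), logical(1))
    if (!any(open)) break
    if (!progress) {
      resid <- vapply(couples[open], function(cp)
        paste0(cp[["red"]], "=", rat_num(rat_get(cur, cp[["red"]]))), "")
      stop("cofactor couples not closable with the given systems: ",
           paste(resid, collapse = ", "))
    }
  }
  ## gross H2 in/out: explicit route H2 plus hydrogenase turnover
  route_h2 <- rat_num(rat_get(net$stoich, "H2"))
  u_fefe <- if ("fefe_a3" %in% names(used)) used[["fefe_a3"]] else 0
  u_nife <- if ("nife_4e" %in% names(used)) used[["nife_4e"]] else 0
  ## forward FeFe-A3 consumes 2 H2 per use, forward NiFe-4e evolves 1;
  ## reversed uses flip sides
  gross_in <- max(0, -route_h2) + 2 * max(0, u_fefe) + max(0, -u_nife)
  gross_out <- max(0, route_h2) + max(0, u_nife) + 2 * max(0, -u_fefe)
  net_h2 <- gross_in - gross_out
  final <- vapply(cur[!vapply(cur, rat_is0, logical(1))], rat_num, numeric(1))
  structure(list(h2_consumed = max(0, net_h2),
                 h2_produced = max(0, -net_h2),
                 gross_h2_in = gross_in, gross_h2_out = gross_out,
                 systems_used = used, closed_stoich = final),
            class = "h2_balance")
}

#' Maximal H2 consumed per mole of substrate for a shipped route
#'
#' Builds the route's net reaction, closes all cofactor couples with
#' the default recycling cascade, and reports the net moles of H2
#' consumed per mole of route substrate.
#'
#' @param route_id One of the ids in [ledger_routes()].
#' @param routes,reactions,species Libraries (defaults shipped).
#' @param systems Recycling cascade.
#' @return Single numeric (exact; negative values mean net evolution).
#' @export
h2_per_substrate <- function(route_id, routes = ledger_routes(),
                             reactions = ledger_reactions(),
                             species = ledger_species(),
                             systems = recycling_systems()) {
  rt <- routes[[route_id]]
  if (is.null(rt)) stop("unknown route: ", route_id)
  net <- net_reaction(rt, reactions, species)
  bal <- apply_recycling(net, systems, reactions, species)
  sub_cf <- rat_num(rat_get(net$stoich, rt$substrate))
  if (sub_cf >= 0) stop("route does not consume its substrate")
  (bal$h2_consumed - bal$h2_produced) / (-sub_cf)
}

#' Summary table of the hydrogen ledger over all shipped routes
#'
#' @inheritParams h2_per_substrate
#' @return Data frame: route_id, substrate, h2_consumed_net,
#'   gross_h2_in, gross_h2_out, and the recycling-system use counts.
#' @export
h2_ledger_report <- function(routes = ledger_routes(),
                             reactions = ledger_reactions(),
                             species = ledger_species(),
                             systems = recycling_systems()) {
  rows <- lapply(routes, function(rt) {
    net <- net_reaction(rt, reactions, species)
    bal <- apply_recycling(net, systems, reactions, species)
    sub_cf <- -rat_num(rat_get(net$stoich, rt$substrate))
    cbind(data.frame(route_id = rt$route_id, substrate = rt$substrate,
                     h2_consumed_net = (bal$h2_consumed - bal$h2_produced) / sub_cf,
                     gross_h2_in = bal$gross_h2_in / sub_cf,
                     gross_h2_out = bal$gross_h2_out / sub_cf,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(bal$systems_used)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
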