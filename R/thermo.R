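#' @importFrom stats rbinom rmultinom runif setNames aggregate
#' @importFrom utils read.delim write.table
NULL

# universal gas constant, kJ mol^-1 K^-1
.RGAS <- 8.314e-3

# species with special treatment in the reaction quotient
.WATER  <- "H2O"
.PROTON <- "H+"

#' Define an anaerobic reaction
#'
#' A reaction is a signed stoichiometry over chemical species (negative
#' coefficients = consumed, positive = formed) together with its
#' standard-condition transformed Gibbs free energy \eqn{\Delta G^{0'}}
#' (pH 7, solutes at 1 mol/L, gases at 1 atm, 25 degC reference set),
#' in kJ per reaction as written.
#'
#' Water (`"H2O"`) and the proton (`"H+"`) are recognised by name and given
#' special treatment when the reaction quotient is evaluated: water activity
#' is fixed at 1 and the proton activity is referenced to 1e-7 (the prime
#' convention), so both terms vanish at pH 7.
#'
#' @param name label for the reaction.
#' @param stoichiometry named numeric vector of signed coefficients, names
#'   are species identifiers (e.g. `c(propionate = -1, H2 = 3)`).
#' @param dg0_prime standard-condition free energy, kJ per reaction.
#' @return an object of class `"reaction"`.
#' @examples
#' pox <- reaction("propionate_oxidation",
#'   c(propionate = -1, H2O = -3, acetate = 1, `HCO3-` = 1, `H+` = 1, H2 = 3),
#'   dg0_prime = 76.1)
#' pox
#' @export
reaction <- function(name, stoichiometry, dg0_prime) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(stoichiometry) || is.null(names(stoichiometry)) ||
      any(!nzchar(names(stoichiometry))))
    stop("'stoichiometry' must be a named numeric vector")
  if (anyDuplicated(names(stoichiometry)))
    stop("duplicate species in stoichiometry")
  if (all(stoichiometry == 0))
    stop("reaction must have at least one nonzero coefficient")
  stopifnot(is.numeric(dg0_prime), length(dg0_prime) == 1L, is.finite(dg0_prime))
  structure(
    list(name = name, stoichiometry = stoichiometry, dg0_prime = dg0_prime),
    class = "reaction")
}

#' @export
print.reaction <- function(x, ...) {
  s <- x$stoichiometry
  fmt <- function(v, sp) {
    co <- ifelse(abs(v) == 1, "", paste0(format(abs(v)), " "))
    paste0(co, sp, collapse = " + ")
  }
  lhs <- fmt(s[s < 0], names(s)[s < 0])
  rhs <- fmt(s[s > 0], names(s)[s > 0])
  cat(sprintf("<reaction> %s\n  %s -> %s\n  dG0' = %+.1f kJ/reaction\n",
              x$name, lhs, rhs, x$dg0_prime))
  invisible(x)
}

#' Define reaction conditions
#'
#' Conditions fix the temperature, the activities of solutes (mol/L) and
#' gases (atm), and the pH. Water activity is always 1 and the proton
#' activity is derived from the pH; supplying either in `activities` is an
#' error.
#'
#' @param temperature temperature in kelvin (default 310.15, i.e. 37 degC).
#' @param activities named numeric vector of species activities; all must be
#'   positive.
#' @param pH the pH (default 7).
#' @return an object of class `"conditions"`.
#' @examples
#' digester_conditions(ph2 = 1e-4)
#' @export
conditions <- function(temperature = 310.15, activities = numeric(), pH = 7) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L, temperature > 0)
  if (length(activities)) {
    if (is.null(names(activities)) || any(!nzchar(names(activities))))
      stop("'activities' must be named")
    if (any(!is.finite(activities)) || any(activities <= 0))
      stop("all activities must be positive and finite")
    if (any(names(activities) %in% c(.WATER, .PROTON)))
      stop("water and proton activities are fixed by convention; ",
           "set pH instead of supplying 'H+'")
  }
  stopifnot(is.numeric(pH), length(pH) == 1L, is.finite(pH))
  structure(list(temperature = temperature,
                 activities = activities, pH = pH),
            class = "conditions")
}

#' @export
print.conditions <- function(x, ...) {
  cat(sprintf("<conditions> T = %.2f K, pH = %g\n", x$temperature, x$pH))
  if (length(x$activities)) {
    a <- x$activities
    cat(paste0("  ", names(a), " = ", format(a, digits = 4), collapse = "\n"),
        "\n")
  }
  invisible(x)
}

#' Mesophilic-digester reference conditions
#'
#' The condition set used throughout the hydrogen partial-pressure sweep:
#' 37 degC (310.15 K), 1 mmol/L acetate and propionate, 20 mmol/L
#' bicarbonate, 0.6 atm methane, pH 7, with the hydrogen partial pressure
#' as the free variable.
#'
#' @param ph2 hydrogen partial pressure in atm, or `NULL` to omit H2 (for
#'   use with [h2_crossover()] and [free_energy_table()], which set it
#'   themselves).
#' @return a [conditions()] object.
#' @export
digester_conditions <- function(ph2 = NULL) {
  a <- c(acetate = 1e-3, propionate = 1e-3, `HCO3-` = 0.02, CH4 = 0.6)
  if (!is.null(ph2)) {
    stopifnot(is.numeric(ph2), length(ph2) == 1L, ph2 > 0)
    a <- c(a, H2 = ph2)
  }
  conditions(temperature = 310.15, activities = a, pH = 7)
}

# signed ln Q of a reaction under conditions; water contributes 0,
# proton contributes nu * ln(10^(pH-7)) ... i.e. activity 10^-pH over 1e-7
.ln_q <- function(rxn, cond) {
  s <- rxn$stoichiometry
  s <- s[s != 0]
  lnq <- 0
  for (sp in names(s)) {
    if (sp == .WATER) next
    if (sp == .PROTON) {
      lnq <- lnq + s[[sp]] * log(10^(-cond$pH) / 1e-7)
      next
    }
    a <- cond$activities[sp]
    if (is.na(a))
      stop("no activity supplied for species '", sp, "'")
    lnq <- lnq + s[[sp]] * log(a[[1L]])
  }
  lnq
}

#' Transformed Gibbs free energy under given conditions
#'
#' Evaluates \eqn{\Delta G' = \Delta G^{0'} + RT \ln Q} where the reaction
#' quotient Q multiplies species activities raised to their signed
#' stoichiometric coefficients, with water at activity 1 and the proton
#' activity referenced to 1e-7 (so the proton term vanishes at pH 7).
#' R = 8.314 J mol^-1 K^-1.
#'
#' @param rxn a [reaction()].
#' @param cond a [conditions()] object supplying an activity for every
#'   participating species other than water and the proton.
#' @return free energy in kJ per reaction (scalar).
#' @examples
#' reg <- std_reactions()
#' delta_g_prime(reg$hydrogenotrophic_methanogenesis,
#'               digester_conditions(ph2 = 1e-4))  # about -32 kJ
#' @export
delta_g_prime <- function(rxn, cond) {
  stopifnot(inherits(rxn, "reaction"), inherits(cond, "conditions"))
  rxn$dg0_prime + .RGAS * cond$temperature * .ln_q(rxn, cond)
}

#' Linear combination of reactions
#'
#' Forms the weighted sum of a list of reactions: stoichiometries are added
#' coefficient-wise (species whose net coefficient cancels to zero are
#' dropped) and the standard free energies are combined with the same
#' weights.
#'
#' @param rxns non-empty list of [reaction()] objects.
#' @param multipliers numeric vector of weights, one per reaction.
#' @param name label for the combined reaction.
#' @return a [reaction()].
#' @examples
#' reg <- std_reactions()
#' combine_reactions(
#'   list(reg$propionate_oxidation, reg$hydrogenotrophic_methanogenesis,
#'        reg$acetoclastic_methanogenesis),
#'   c(1, 0.75, 1))  # complete propionate conversion, -56.6 kJ
#' @export
combine_reactions <- function(rxns, multipliers, name = "combined") {
  if (!is.list(rxns) || length(rxns) == 0L)
    stop("'rxns' must be a non-empty list of reactions")
  stopifnot(length(multipliers) == length(rxns), is.numeric(multipliers))
  stoich <- numeric()
  dg0 <- 0
  for (i in seq_along(rxns)) {
    r <- rxns[[i]]
    stopifnot(inherits(r, "reaction"))
    m <- multipliers[i]
    for (sp in names(r$stoichiometry)) {
      stoich[sp] <- (if (is.na(stoich[sp])) 0 else stoich[sp]) +
        m * r$stoichiometry[[sp]]
    }
    dg0 <- dg0 + m * r$dg0_prime
  }
  stoich <- stoich[abs(stoich) > 1e-12]
  structure(list(name = name, stoichiometry = stoich, dg0_prime = dg0),
            class = "reaction")
}

#' The five-reaction registry
#'
#' The named anaerobic reactions at the core of syntrophic propionate
#' degradation, with literature standard-condition free energies
#' (kJ per reaction as written):
#'
#' * `propionate_oxidation`: propionate- + 3 H2O -> acetate- + HCO3- +
#'   H+ + 3 H2 (+76.1)
#' * `hydrogenotrophic_methanogenesis`: 4 H2 + HCO3- + H+ -> CH4 +
#'   3 H2O (-135.6)
#' * `acetoclastic_methanogenesis`: acetate- + H2O -> CH4 + HCO3- (-31.0)
#' * `sao` (syntrophic acetate oxidation): acetate- + 4 H2O -> 2 HCO3- +
#'   4 H2 + H+ (+104.6)
#' * `aha` (autotrophic homoacetogenesis): the exact reverse of `sao`
#'   (-104.6)
#'
#' The registry ships as a YAML config under `inst/extdata/reactions.yaml`
#' and is validated at load: `aha` must be the exact negation of `sao`, and
#' `sao` + `hydrogenotrophic_methanogenesis` must equal
#' `acetoclastic_methanogenesis` in both stoichiometry and free energy.
#'
#' @return named list of five [reaction()] objects.
#' @export
std_reactions <- function() {
  path <- system.file("extdata", "reactions.yaml", package = "propsyn",
                      mustWork = TRUE)
  reg <- read_reactions(path)
  .validate_registry(reg)
  reg
}

.validate_registry <- function(reg) {
  need <- c("propionate_oxidation", "hydrogenotrophic_methanogenesis",
            "acetoclastic_methanogenesis", "sao", "aha")
  if (!all(need %in% names(reg)))
    stop("registry is missing reactions: ",
         paste(setdiff(need, names(reg)), collapse = ", "))
  by_name <- function(v) v[order(names(v))]
  neg <- combine_reactions(list(reg$sao), -1)
  if (!isTRUE(all.equal(by_name(neg$stoichiometry),
                        by_name(reg$aha$stoichiometry))) ||
      abs(neg$dg0_prime - reg$aha$dg0_prime) > 1e-9)
    stop("registry invariant violated: aha must be the negation of sao")
  am <- combine_reactions(list(reg$sao, reg$hydrogenotrophic_methanogenesis),
                          c(1, 1))
  if (!isTRUE(all.equal(by_name(am$stoichiometry),
                        by_name(reg$acetoclastic_methanogenesis$stoichiometry))) ||
      abs(am$dg0_prime - reg$acetoclastic_methanogenesis$dg0_prime) > 1e-9)
    stop("registry invariant violated: sao + hydrogenotrophic ",
         "methanogenesis must equal acetoclastic methanogenesis")
  invisible(reg)
}

#' Read or write reaction definitions
#'
#' Reactions are stored as a YAML list of documents, each with fields
#' `name`, `stoichiometry` (a map species -> signed coefficient) and
#' `dg0_prime`.
#'
#' @param path file path.
#' @return `read_reactions()` returns a named list of [reaction()]s;
#'   `write_reactions()` returns `path` invisibly.
#' @export
read_reactions <- function(path) {
  docs <- yaml::read_yaml(path)
  out <- lapply(docs, function(d)
    reaction(d$name, unlist(d$stoichiometry), d$dg0_prime))
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

#' @rdname read_reactions
#' @param rxns named list of [reaction()] objects.
#' @export
write_reactions <- function(rxns, path) {
  docs <- lapply(unname(rxns), function(r)
    list(name = r$name, stoichiometry = as.list(r$stoichiometry),
         dg0_prime = r$dg0_prime))
  yaml::write_yaml(docs, path)
  invisible(path)
}

#' Hydrogen partial pressure at thermodynamic equilibrium
#'
#' For a reaction with nonzero hydrogen stoichiometry \eqn{\nu}, the free
#' energy is \eqn{\Delta G'(p_{H_2}) = a + \nu RT \ln p_{H_2}} with `a` the
#' H2-independent part evaluated from `cond`. The unique root
#' \eqn{p_{H_2} = \exp(-a / (\nu RT))} is returned in atm.
#'
#' @param rxn a [reaction()] containing H2.
#' @param cond [conditions()] fixing all non-H2 activities (any H2 entry is
#'   ignored).
#' @return hydrogen partial pressure in atm.
#' @examples
#' h2_crossover(std_reactions()$sao, digester_conditions())  # about 5e-5
#' @export
h2_crossover <- function(rxn, cond) {
  stopifnot(inherits(rxn, "reaction"), inherits(cond, "conditions"))
  nu <- rxn$stoichiometry["H2"]
  if (is.na(nu) || nu == 0)
    stop("reaction '", rxn$name, "' has no H2 term; ",
         "its free energy does not depend on pH2")
  cond$activities <- cond$activities[names(cond$activities) != "H2"]
  cond$activities <- c(cond$activities, H2 = 1)
  a <- delta_g_prime(rxn, cond)            # dG' at pH2 = 1 atm
  exp(-a / (nu[[1L]] * .RGAS * cond$temperature))
}

#' Free-energy table across a hydrogen partial-pressure sweep
#'
#' Evaluates [delta_g_prime()] for each reaction at each hydrogen partial
#' pressure, holding all other conditions fixed.
#'
#' @param rxns named list of [reaction()] objects.
#' @param cond base [conditions()]; any H2 entry is overridden row-wise.
#' @param ph2_values positive hydrogen partial pressures in atm (rows).
#' @return object of class `"free_energy_table"`: a numeric matrix
#'   (rows = pH2 values, columns = reactions, cells = kJ per reaction)
#'   with attribute `ph2` holding the numeric pressures. Printed values are
#'   rounded to the nearest integer kJ (ties away from zero); the stored
#'   cells are unrounded.
#' @examples
#' free_energy_table(std_reactions(), digester_conditions(),
#'                   c(1e-4, 5e-5, 1e-5))
#' @export
free_energy_table <- function(rxns, cond, ph2_values) {
  stopifnot(is.list(rxns), length(rxns) > 0L,
            is.numeric(ph2_values), length(ph2_values) > 0L,
            all(ph2_values > 0))
  if (is.null(names(rxns)))
    names(rxns) <- vapply(rxns, `[[`, "", "name")
  cells <- matrix(NA_real_, nrow = length(ph2_values), ncol = length(rxns),
                  dimnames = list(format(ph2_values, scientific = TRUE,
                                         digits = 3),
                                  names(rxns)))
  base_act <- cond$activities[names(cond$activities) != "H2"]
  for (i in seq_along(ph2_values)) {
    ci <- cond
    ci$activities <- c(base_act, H2 = ph2_values[i])
    for (j in seq_along(rxns))
      cells[i, j] <- delta_g_prime(rxns[[j]], ci)
  }
  structure(cells, ph2 = ph2_values, class = c("free_energy_table", "matrix"))
}

# round to integer, ties away from zero (gel-table display convention)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' @export
print.free_energy_table <- function(x, ...) {
  m <- round_half_away(unclass(x))
  storage.mode(m) <- "integer"
  attr(m, "ph2") <- NULL
  cat("Gibbs free energies [kJ/reaction] by hydrogen partial pressure [atm]\n")
  print(m)
  invisible(x)
}

#' Exergonic hydrogen window of a syntrophic pair
#'
#' For a H2-producing reaction (positive H2 coefficient) and a H2-consuming
#' reaction (negative H2 coefficient), returns the open interval of hydrogen
#' partial pressures in which both are exergonic (dG' < 0): the lower bound
#' is the consumer's crossover, the upper bound the producer's. If the lower
#' bound is not below the upper, there is no window and the interval is
#' flagged empty.
#'
#' @param producing [reaction()] with positive H2 coefficient.
#' @param consuming [reaction()] with negative H2 coefficient.
#' @param cond [conditions()] fixing all non-H2 activities.
#' @return list with elements `lower`, `upper` (atm) and logical `empty`.
#' @examples
#' reg <- std_reactions()
#' h2_window(reg$propionate_oxidation,
#'           reg$hydrogenotrophic_methanogenesis, digester_conditions())
#' @export
h2_window <- function(producing, consuming, cond) {
  nu_p <- producing$stoichiometry["H2"]
  nu_c <- consuming$stoichiometry["H2"]
  if (is.na(nu_p) || nu_p <= 0)
    stop("'producing' must have a positive H2 coefficient")
  if (is.na(nu_c) || nu_c >= 0)
    stop("'consuming' must have a negative H2 coefficient")
  lower <- h2_crossover(consuming, cond)
  upper <- h2_crossover(producing, cond)
  list(lower = lower, upper = upper, empty = lower >= upper)
}
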