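#' Define a mass-action reaction
#'
#' A reaction is described by integer stoichiometries of its reactants and
#' products (named by species) and a stochastic rate constant `c` in units of
#' per time (zeroth and first order) or per time per pair (second order).
#' Total reactant molecularity at most 2 is supported, covering zeroth-order
#' production, first-order conversion/decay, heterodimerization `A + B -> ...`
#' and homodimerization `2A -> ...`.
#'
#' @param reactants named numeric vector of reactant stoichiometries
#'   (may be empty for zeroth-order production).
#' @param products named numeric vector of product stoichiometries
#'   (may be empty for pure degradation).
#' @param rate non-negative stochastic rate constant.
#' @return An object of class `"reaction"`.
#' @examples
#' reaction(c(S1 = 2), c(S2 = 1), rate = 0.002)
#' @export
reaction <- function(reactants = numeric(), products = numeric(), rate) {
  stoich_ok <- function(x, what) {
    if (length(x) == 0) return(invisible())
    if (is.null(names(x)) || any(!nzchar(names(x))))
      stop(what, " stoichiometry must be a named vector", call. = FALSE)
    if (any(x < 0) || any(x != round(x)))
      stop(what, " stoichiometry must be non-negative integers", call. = FALSE)
  }
  stoich_ok(reactants, "reactant")
  stoich_ok(products, "product")
  if (length(reactants) + length(products) == 0)
    stop("a reaction needs at least one reactant or product", call. = FALSE)
  if (!is.numeric(rate) || length(rate) != 1 || is.na(rate) || rate < 0)
    stop("'rate' must be a single non-negative number", call. = FALSE)
  if (sum(reactants) > 2)
    stop("total reactant molecularity above 2 is not supported", call. = FALSE)
  structure(list(reactants = reactants, products = products, rate = rate),
            class = "reaction")
}

#' Assemble a reaction network
#'
#' Collects species, mass-action reactions and initial copy numbers into a
#' network object used by the simulator and the inference drivers.
#'
#' @param species character vector of unique species names.
#' @param reactions list of [reaction()] objects; every species they
#'   reference must appear in `species`.
#' @param initial_state non-negative integer copy numbers, one per species.
#' @param dimer propensity convention for homodimerization `2A -> ...`:
#'   `"half"` (default) uses the combinatorial form `c * n * (n - 1) / 2`,
#'   `"full"` uses `c * n * (n - 1)`.
#' @return An object of class `"reaction_network"` with components
#'   `species`, `reactions`, `rates`, `initial_state` and the stoichiometry
#'   matrices `reactants` / `products` (reactions x species).
#' @seealso [system1_network()], [system2_network()], [propensity()]
#' @export
reaction_network <- function(species, reactions, initial_state,
                             dimer = c("half", "full")) {
  dimer <- match.arg(dimer)
  if (anyDuplicated(species)) stop("species names must be unique", call. = FALSE)
  if (!is.list(reactions) || !all(vapply(reactions, inherits, TRUE, "reaction")))
    stop("'reactions' must be a list of reaction() objects", call. = FALSE)
  if (length(initial_state) != length(species))
    stop("'initial_state' length must equal the number of species", call. = FALSE)
  if (any(initial_state < 0) || any(initial_state != round(initial_state)))
    stop("'initial_state' must be non-negative integers", call. = FALSE)
  m <- length(reactions); S <- length(species)
  R <- P <- matrix(0L, m, S, dimnames = list(NULL, species))
  for (j in seq_len(m)) {
    r <- reactions[[j]]
    unknown <- setdiff(c(names(r$reactants), names(r$products)), species)
    if (length(unknown))
      stop("reaction ", j, " references unknown species: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    R[j, names(r$reactants)] <- as.integer(r$reactants)
    P[j, names(r$products)] <- as.integer(r$products)
  }
  structure(list(species = species, reactions = reactions,
                 rates = vapply(reactions, `[[`, numeric(1), "rate"),
                 initial_state = as.numeric(initial_state),
                 reactants = R, products = P, dimer = dimer),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("Mass-action reaction network:", length(x$species), "species,",
      nrow(x$reactants), "reactions\n")
  side <- function(st) {
    nz <- which(st > 0)
    if (!length(nz)) return("0")
    paste(ifelse(st[nz] > 1, paste0(st[nz], " "), ""), x$species[nz],
          sep = "", collapse = " + ")
  }
  for (j in seq_len(nrow(x$reactants)))
    cat(sprintf("  R%d: %s -> %s   (c = %g)\n", j, side(x$reactants[j, ]),
                side(x$products[j, ]), x$rates[j]))
  cat("  initial state:",
      paste(x$species, x$initial_state, sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Mass-action propensity of one reaction
#'
#' Returns the instantaneous hazard of reaction `j` firing in the given
#' copy-number state: `c` for zeroth order, `c * n_A` for `A -> ...`,
#' `c * n_A * n_B` for `A + B -> ...` and `c * n_A * (n_A - 1) / 2`
#' (or without the 1/2 under the `"full"` convention) for `2A -> ...`.
#'
#' @param network a [reaction_network()].
#' @param state non-negative integer copy-number vector.
#' @param j reaction index.
#' @return A single non-negative number.
#' @examples
#' net <- system1_network()
#' propensity(net, c(10000, 0, 0), 1)  # 0.1 * 10000
#' @export
propensity <- function(network, state, j) {
  stopifnot(inherits(network, "reaction_network"))
  if (length(state) != length(network$species))
    stop("'state' length must equal the number of species", call. = FALSE)
  if (any(state < 0)) stop("negative copy numbers in 'state'", call. = FALSE)
  if (length(j) != 1 || j < 1 || j > nrow(network$reactants))
    stop("invalid reaction index", call. = FALSE)
  r <- network$reactants[j, ]
  c_j <- network$rates[j]
  nz <- which(r > 0)
  if (length(nz) == 0) return(c_j)
  if (length(nz) == 2) return(c_j * state[nz[1]] * state[nz[2]])
  n <- state[nz]
  if (r[nz] == 1) return(c_j * n)
  a <- c_j * n * (n - 1)
  if (network$dimer == "half") a / 2 else a
}

#' Benchmark system 1: reversible dimerization with decay
#'
#' Four reactions over three species: decay `S1 -> 0` (c1 = 0.1),
#' dimerization `2 S1 -> S2` (c2 = 0.002), dissociation `S2 -> 2 S1`
#' (c3 = 0.5) and conversion `S2 -> S3` (c4 = 0.04), started from
#' copy numbers (10000, 0, 0).
#'
#' @return A [reaction_network()].
#' @export
system1_network <- function() {
  reaction_network(
    species = c("S1", "S2", "S3"),
    reactions = list(
      reaction(c(S1 = 1), numeric(),  rate = 0.1),
      reaction(c(S1 = 2), c(S2 = 1),  rate = 0.002),
      reaction(c(S2 = 1), c(S1 = 2),  rate = 0.5),
      reaction(c(S2 = 1), c(S3 = 1),  rate = 0.04)),
    initial_state = c(10000, 0, 0))
}

#' Benchmark system 2: prokaryotic auto-regulatory gene network
#'
#' Eight reactions over five species (DNA, mRNA, P, P2, DNA.P2): reversible
#' repressor binding `DNA + P2 <-> DNA.P2` (c1 = 0.1, c2 = 0.7), catalytic
#' transcription `DNA -> DNA + mRNA` (c3 = 0.35), mRNA degradation
#' (c4 = 0.01), reversible dimerization `2P <-> P2` (c5 = 0.1, c6 = 0.9),
#' production from mRNA (c7 = 0.2) and protein degradation `P -> 0`
#' (c8 = 0.01).  Initial copy numbers are (10, 100, 100, 800, 100).
#'
#' As printed in the source reaction list, reaction 7 produces the dimer
#' directly (`mRNA -> mRNA + P2`); set `r7_product = "P"` for the
#' conventional translation reading `mRNA -> mRNA + P`.
#'
#' @param r7_product product species of reaction 7, `"P2"` (default) or `"P"`.
#' @return A [reaction_network()].
#' @export
system2_network <- function(r7_product = c("P2", "P")) {
  r7_product <- match.arg(r7_product)
  r7 <- c(mRNA = 1, 1)
  names(r7)[2] <- r7_product
  reaction_network(
    species = c("DNA", "mRNA", "P", "P2", "DNA.P2"),
    reactions = list(
      reaction(c(DNA = 1, P2 = 1), c(DNA.P2 = 1),      rate = 0.1),
      reaction(c(DNA.P2 = 1),      c(DNA = 1, P2 = 1), rate = 0.7),
      reaction(c(DNA = 1),         c(DNA = 1, mRNA = 1), rate = 0.35),
      reaction(c(mRNA = 1),        numeric(),          rate = 0.01),
      reaction(c(P = 2),           c(P2 = 1),          rate = 0.1),
      reaction(c(P2 = 1),          c(P = 2),           rate = 0.9),
      reaction(c(mRNA = 1),        r7,                 rate = 0.2),
      reaction(c(P = 1),           numeric(),          rate = 0.01)),
    initial_state = c(10, 100, 100, 800, 100))
}

#' Replace the rate constants of a network
#'
#' @param network a [reaction_network()].
#' @param rates numeric vector, one non-negative rate per reaction.
#' @return The network with updated rates.
#' @export
set_rates <- function(network, rates) {
  stopifnot(inherits(network, "reaction_network"))
  if (length(rates) != length(network$rates))
    stop("'rates' must have one entry per reaction", call. = FALSE)
  if (any(rates < 0) || any(!is.finite(rates)))
    stop("'rates' must be finite and non-negative", call. = FALSE)
  network$rates <- as.numeric(rates)
  for (j in seq_along(rates)) network$reactions[[j]]$rate <- rates[j]
  network
}

#' Read or write a reaction network file
#'
#' Networks are stored as YAML (`.yml`/`.yaml`) or JSON with keys
#' `species` (character vector), `reactions` (list with fields `reactants`,
#' `products` -- maps species -> stoichiometry -- and `rate`),
#' `initial_state`, and optionally `dimer`.  The two formats round-trip
#' losslessly through [write_network()].
#'
#' @param path file path; format chosen by extension.
#' @return `read_network()` returns a [reaction_network()];
#'   `write_network()` returns `path` invisibly.
#' @export
read_network <- function(path) {
  spec <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  else yaml::read_yaml(path)
  as_stoich <- function(x) {
    if (is.null(x) || length(x) == 0) return(numeric())
    unlist(x)
  }
  reactions <- lapply(spec$reactions, function(r)
    reaction(as_stoich(r$reactants), as_stoich(r$products), r$rate))
  reaction_network(species = unlist(spec$species), reactions = reactions,
                   initial_state = unlist(spec$initial_state),
                   dimer = if (is.null(spec$dimer)) "half" else spec$dimer)
}

#' @param network a [reaction_network()] to serialize.
#' @rdname read_network
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "reaction_network"))
  spec <- list(
    species = as.list(network$species),
    reactions = lapply(network$reactions, function(r)
      list(reactants = as.list(r$reactants), products = as.list(r$products),
           rate = r$rate)),
    initial_state = as.list(network$initial_state),
    dimer = network$dimer)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  else yaml::write_yaml(spec, path)
  invisible(path)
}
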