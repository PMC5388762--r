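## Shared fixtures: the reference network (loaded once per session) and
## small toy networks built in code.

.fixture_env <- new.env(parent = emptyenv())

ref_model <- function() {
  if (is.null(.fixture_env$ref))
    .fixture_env$ref <- reference_network()
  .fixture_env$ref
}

ref_state <- function(model = ref_model()) {
  st <- initial_state(model)
  st[["GLC_e"]] <- 35
  st[["GLN_e"]] <- 6
  st
}

toy_species <- function(id, conc, type = "dynamic", compartment = "cytosol")
  list(id = id, compartment = compartment, type = type, conc = conc)

## closed two-metabolite cycle: A <-> B (reversible) and B -> A; mass is
## conserved exactly. Optional growth block for the cell-equation tests.
toy_cycle <- function(growth = NULL) {
  load_network(list(
    metadata = list(name = "toy-cycle"),
    growth = growth,
    species = list(toy_species("A", 2), toy_species("B", 1)),
    reactions = list(
      list(id = "R1", form = "mm_rev", explicit_vr = TRUE,
           stoich = list(A = -1, B = 1), substrates = list("A"),
           products = list("B"),
           params = list(Km_A = 1, Km_B = 1, Vf = 1, Vr = 0.5, Veq = 2)),
      list(id = "R2", form = "mm_irr",
           stoich = list(B = -1, A = 1), substrates = list("B"),
           products = list("A"),
           params = list(Km_B = 1, Vf = 0.3)))))
}

## boundary-fed linear system: X_e -> S -> (sink), both mass action, so
## S(t) solves dS/dt = u - k S in closed form.
toy_linear <- function(u = 1, k = 0.5, s0 = 1, xe = 5) {
  load_network(list(
    metadata = list(name = "toy-linear"),
    panel = list("S"),
    species = list(toy_species("X_e", xe, type = "boundary",
                               compartment = "extracellular"),
                   toy_species("S", s0)),
    reactions = list(
      list(id = "IN", form = "ma_irr",
           stoich = list(X_e = -1, S = 1), substrates = list("X_e"),
           products = list("S"), params = list(Vf = u / xe)),
      list(id = "OUT", form = "ma_irr",
           stoich = list(S = -1), substrates = list("S"),
           products = list(), params = list(Vf = k)))))
}

## boundary-fed chain with two reversible steps: RAB operates near
## equilibrium (its Vf/Vr pair is confounded in any steady-state
## observable), RBC is strongly displaced (identifiable).
toy_chain <- function() {
  load_network(list(
    metadata = list(name = "toy-chain"),
    panel = list("A", "B", "C"),
    species = list(toy_species("X_e", 1, type = "boundary",
                               compartment = "extracellular"),
                   toy_species("A", 1), toy_species("B", 1),
                   toy_species("C", 1)),
    reactions = list(
      list(id = "RIN", form = "ma_irr",
           stoich = list(X_e = -1, A = 1), substrates = list("X_e"),
           products = list("A"), params = list(Vf = 1)),
      list(id = "RAB", form = "mm_rev", explicit_vr = TRUE,
           stoich = list(A = -1, B = 1), substrates = list("A"),
           products = list("B"),
           params = list(Km_A = 0.5, Km_B = 0.5, Vf = 60, Vr = 57,
                         Veq = 60 / 57)),
      list(id = "RBC", form = "mm_rev", explicit_vr = TRUE,
           stoich = list(B = -1, C = 1), substrates = list("B"),
           products = list("C"),
           params = list(Km_B = 1, Km_C = 1, Vf = 4.4, Vr = 0.4,
                         Veq = 11)),
      list(id = "ROUT", form = "mm_irr",
           stoich = list(C = -1), substrates = list("C"),
           products = list(), params = list(Km_C = 1, Vf = 2)))))
}

## constant-nutrient model (ATP/GLC/GLN fixed): the growth equation sees a
## constant lambda, so the logistic-with-death solution is closed form.
toy_growth <- function(growth) {
  load_network(list(
    metadata = list(name = "toy-growth"),
    growth = growth,
    species = list(toy_species("ATP", 5, type = "fixed"),
                   toy_species("GLC", 10, type = "fixed"),
                   toy_species("GLN", 2, type = "fixed"),
                   toy_species("A", 1)),
    reactions = list(
      list(id = "R1", form = "mm_irr",
           stoich = list(A = -1), substrates = list("A"),
           products = list(), params = list(Km_A = 1, Vf = 1e-6)))))
}

## random concentration state over given species names (positive)
random_state <- function(ids, seed) {
  set.seed(seed)
  stats::setNames(stats::runif(length(ids), 0.01, 5), ids)
}
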