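#' Class-conditional steady-state distributions from a problem definition
#'
#' Composes the BNp machinery into a two-class classification problem: for
#' each class, build the perturbed Boolean network with its stuck-at
#' mutations, average over extracellular-signal scenarios, take the exact
#' steady state and marginalize to the observed features.
#'
#' A class definition is a list with elements
#' \describe{
#'   \item{`p_pert`}{perturbation probability for the class,}
#'   \item{`fixed`}{named 0/1 vector of stuck-at mutations (optional),}
#'   \item{`scenarios`}{list of named 0/1 vectors fixing input nodes, one
#'     per scenario (optional; a single empty scenario by default),}
#'   \item{`weights`}{scenario weights (optional; uniform by default),}
#'   \item{`input_mode`}{`"ssd"` to mix scenario steady states (a
#'     population of cells, each in a stable signaling context) or
#'     `"transition"` to mix scenario transition matrices, i.e. a single
#'     chain whose input is redrawn independently each step (a transient
#'     stochastic event such as a DNA lesion).  Default `"ssd"`.}
#' }
#'
#' @param network A [boolean_network()].
#' @param features Ordered character vector of observed nodes.
#' @param class0,class1 Class definitions as described above.
#' @param c Class-0 prior probability.
#' @return A [classification_problem()] over `2^length(features)` bins.
#' @export
class_conditional_ssd <- function(network, features, class0, class1,
                                  c = 0.5) {
  p0 <- class_ssd(network, features, class0)
  p1 <- class_ssd(network, features, class1)
  classification_problem(c, p0, p1)
}

class_ssd <- function(network, features, cls) {
  p_pert <- cls$p_pert
  fixed <- cls$fixed
  scenarios <- cls$scenarios
  if (is.null(scenarios)) scenarios <- list(NULL)
  weights <- cls$weights
  if (is.null(weights)) weights <- rep(1 / length(scenarios),
                                       length(scenarios))
  mode <- if (is.null(cls$input_mode)) "ssd" else cls$input_mode
  pert <- if (is.null(cls$perturbation)) "single" else cls$perturbation
  models <- lapply(scenarios, function(sc)
    bnp_model(network, p_pert, fixed = c(fixed, sc), perturbation = pert))
  if (mode == "ssd") {
    margs <- lapply(models, function(m) marginalize(bnp_steady_state(m),
                                                    features))
    scenario_mixture(margs, weights)
  } else if (mode == "transition") {
    free <- models[[1]]$network$nodes
    for (m in models)
      if (!identical(m$network$nodes, free))
        stop("transition-mode scenarios must share the same free nodes")
    tpms <- lapply(models, build_transition_matrix)
    P <- Reduce(`+`, Map(`*`, tpms, weights))
    marginalize(steady_state(P, free), features)
  } else stop("unknown input_mode: ", mode)
}

#' The mammalian cell-cycle classification problem
#'
#' Normal class: the ten-node wild-type cell-cycle network at perturbation
#' probability 0.01; the extracellular growth signal CycD is by default a
#' free input that holds its value under the logic update and changes only
#' through perturbation (a symmetric Bernoulli source in steady state).
#' Mutated class: CycD, Rb and p27 permanently down-regulated (stuck at 0)
#' at perturbation probability 0.05, so the cell can cycle in the absence
#' of any growth factor.  Both steady states are marginalized to the seven
#' observed genes E2F, CycE, CycA, Cdc20, Cdh1, UbcH10, CycB (128 bins).
#'
#' @param c Class-0 (normal) prior probability.
#' @param cycd Handling of the free CycD input in the normal class:
#'   `"held"` (default) keeps CycD as a free perturbable node; `"mixture"`
#'   averages the steady states with CycD fixed off and on, using
#'   `cycd_weights`.
#' @param cycd_weights Weights for the CycD = 0 / CycD = 1 scenarios.
#' @param perturbation Perturbation semantics, see [bnp_model()].
#' @return A [classification_problem()].
#' @export
cellcycle_problem <- function(c = 0.5, cycd = c("held", "mixture"),
                              cycd_weights = c(0.5, 0.5),
                              perturbation = "single") {
  cycd <- match.arg(cycd)
  net <- read_bnet(system.file("extdata", "cellcycle.bnet",
                               package = "mkdipobc"))
  features <- c("E2F", "CycE", "CycA", "Cdc20", "Cdh1", "UbcH10", "CycB")
  normal <- if (cycd == "mixture")
    list(p_pert = 0.01,
         scenarios = list(c(CycD = 0), c(CycD = 1)),
         weights = cycd_weights, input_mode = "ssd",
         perturbation = perturbation)
  else list(p_pert = 0.01, perturbation = perturbation)
  mutated <- list(p_pert = 0.05, fixed = c(CycD = 0, Rb = 0, p27 = 0),
                  perturbation = perturbation)
  class_conditional_ssd(net, features, normal, mutated, c = c)
}

#' The TP53 classification problem
#'
#' Normal class: the five-node p53/Mdm2 network at perturbation probability
#' 0.01, with the DNA double-strand-break input weighted 0.95 (absent) /
#' 0.05 (present).  Mutated class: P53 permanently down-regulated (stuck at
#' 0) at perturbation probability 0.05, same input weighting.  Both steady
#' states are marginalized to ATM, Wip1, Mdm2 (8 bins).
#'
#' By default the two scenario steady states are mixed
#' (`input_mode = "ssd"`: two sub-populations of cells, with and without a
#' persistent lesion).  `input_mode = "transition"` instead mixes the two
#' scenario transition matrices, i.e. a single chain whose input is redrawn
#' independently at every step.
#'
#' @param c Class-0 (normal) prior probability.
#' @param input_mode `"ssd"` (default) or `"transition"`; see Details.
#' @param dsb_weights Weights for the dna_dsb = 0 / dna_dsb = 1 scenarios.
#' @param perturbation Perturbation semantics, see [bnp_model()].
#' @return A [classification_problem()].
#' @export
tp53_problem <- function(c = 0.5, input_mode = c("ssd", "transition"),
                         dsb_weights = c(0.95, 0.05),
                         perturbation = "single") {
  input_mode <- match.arg(input_mode)
  net <- read_bnet(system.file("extdata", "tp53.bnet", package = "mkdipobc"))
  features <- c("ATM", "Wip1", "Mdm2")
  scen <- list(c(dna_dsb = 0), c(dna_dsb = 1))
  normal <- list(p_pert = 0.01, scenarios = scen, weights = dsb_weights,
                 input_mode = input_mode, perturbation = perturbation)
  mutated <- list(p_pert = 0.05, fixed = c(P53 = 0), scenarios = scen,
                  weights = dsb_weights, input_mode = input_mode,
                  perturbation = perturbation)
  class_conditional_ssd(net, features, normal, mutated, c = c)
}
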