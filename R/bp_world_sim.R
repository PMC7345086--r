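# Stochastic simulator of the bridge-peptide (BP) feedback mechanism in a
# GC-biased RNA-peptide world. Each cycle: (1) aminoacylation — every
# uncharged RNA is charged either by BP-mediated Arg charging (probability
# increasing with the BP count and the molecule's GC fraction) or by the
# "chemical code" (amino acids drawn in proportion to prebiotic abundance);
# (2) hybridization-dependent peptide (HDP) formation — charged RNAs are
# grouped at random and their residues joined into peptides; (3) stability
# selection — peptides survive with a bonus if they satisfy the BP motif,
# RNAs survive with a GC-dependent probability, and the RNA pool is
# replenished to its nominal size. All rates and functional forms are free
# parameters of the model; the mechanism itself is qualitative.

#' Default chemical-code sampling weights
#'
#' Midpoints of the panel (a) prebiotic abundance ranges, with a small
#' floor for amino acids the table does not report (avoids structural
#' zeros while keeping them rare).
#'
#' @param floor weight assigned to unreported amino acids.
#' @return named numeric vector over the 20 amino acids.
#' @export
default_aa_weights <- function(floor = 0.005) {
  mid <- abundance_summary(load_abundance(), "a", "midpoint")
  w <- stats::setNames(rep(floor, length(AMINO_ACIDS)), AMINO_ACIDS)
  w[names(mid)] <- mid
  w
}

#' Simulator configuration
#'
#' Validated parameter set for [run_simulation()]. With `bp_bias = 0` the
#' model reduces exactly to chemical-code incorporation.
#'
#' @param n_rna RNA pool size (held constant by replenishment).
#' @param rna_length bases per RNA molecule.
#' @param p_gc per-base probability of G or C (split evenly G/C; A/U
#'   likewise).
#' @param aa_weights chemical-code sampling weights (named, non-negative,
#'   positive sum); defaults to [default_aa_weights()].
#' @param bp_bias beta >= 0, strength of BP-mediated Arg charging: an
#'   uncharged RNA is Arg-charged with probability
#'   min(1, beta * n_bp / n_rna * gc_fraction).
#' @param peptide_len_range integer (min, max) residues per peptide.
#' @param base_survival per-cycle survival probability of peptides and RNAs.
#' @param survival_bonus multiplier on survival for BP peptides (capped at 1).
#' @param gc_slope slope of the linear GC-stability adjustment to RNA
#'   survival: survival = base_survival + gc_slope * (gc_fraction - 0.5),
#'   clamped to [0, 1].
#' @param n_cycles cycles to run.
#' @param bp_initial number of seed BPs (Arg-Gly-Gly-Ala-Asp) present at
#'   cycle 0.
#' @param bp_motif `"arg_asp"` (default: a BP needs >= 1 Arg and >= 1 Asp)
#'   or `"arg_only"`.
#' @param bp_min_length minimum residues for a peptide to count as a BP.
#' @param seed integer RNG seed (NULL for the current RNG state).
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_rna = 1000, rna_length = 20, p_gc = 0.7,
                       aa_weights = default_aa_weights(), bp_bias = 5,
                       peptide_len_range = c(2, 6), base_survival = 0.8,
                       survival_bonus = 1.25, gc_slope = 0.2,
                       n_cycles = 200, bp_initial = 5,
                       bp_motif = c("arg_asp", "arg_only"),
                       bp_min_length = 3, seed = NULL) {
  bp_motif <- match.arg(bp_motif)
  stopifnot(n_rna >= 1, rna_length >= 1,
            p_gc >= 0, p_gc <= 1,
            is.numeric(aa_weights), !is.null(names(aa_weights)),
            all(aa_weights >= 0), sum(aa_weights) > 0,
            bp_bias >= 0,
            length(peptide_len_range) == 2L,
            peptide_len_range[1] >= 1,
            peptide_len_range[1] <= peptide_len_range[2],
            base_survival >= 0, base_survival <= 1,
            survival_bonus >= 0, n_cycles >= 0, bp_initial >= 0,
            bp_min_length >= 1)
  names(aa_weights) <- aa_to_three(names(aa_weights))
  structure(list(n_rna = as.integer(n_rna),
                 rna_length = as.integer(rna_length), p_gc = p_gc,
                 aa_weights = aa_weights, bp_bias = bp_bias,
                 peptide_len_range = as.integer(peptide_len_range),
                 base_survival = base_survival,
                 survival_bonus = survival_bonus, gc_slope = gc_slope,
                 n_cycles = as.integer(n_cycles),
                 bp_initial = as.integer(bp_initial), bp_motif = bp_motif,
                 bp_min_length = as.integer(bp_min_length), seed = seed),
            class = "sim_config")
}

#' Bridge-peptide motif predicate
#'
#' Under the default motif a bridge peptide must be at least
#' `min_length` residues long and contain at least one Arg (RNA binding)
#' and one Asp (recruitment of free Arg); the prototype is
#' Arg-Gly-Gly-Ala-Asp. The `"arg_only"` motif drops the Asp requirement.
#'
#' @param residues character vector of amino-acid codes (a peptide).
#' @param motif `"arg_asp"` or `"arg_only"`.
#' @param min_length minimum peptide length.
#' @return logical.
#' @examples
#' is_bridge_peptide(c("Arg", "Gly", "Gly", "Ala", "Asp"))  # TRUE
#' @export
is_bridge_peptide <- function(residues, motif = c("arg_asp", "arg_only"),
                              min_length = 3) {
  motif <- match.arg(motif)
  if (!length(residues)) stop("empty peptide")
  residues <- aa_to_three(residues)
  if (length(residues) < min_length) return(FALSE)
  has_arg <- "Arg" %in% residues
  if (motif == "arg_only") return(has_arg)
  has_arg && "Asp" %in% residues
}

.new_rna <- function(n, cfg) {
  if (n == 0L) {
    return(list(seq = character(0), gc = numeric(0)))
  }
  # per-base: G or C with prob p_gc (even split), A or U likewise
  p <- c(G = cfg$p_gc / 2, C = cfg$p_gc / 2,
         A = (1 - cfg$p_gc) / 2, U = (1 - cfg$p_gc) / 2)
  bases <- sample(names(p), n * cfg$rna_length, replace = TRUE, prob = p)
  m <- matrix(bases, nrow = n)
  list(seq = apply(m, 1, paste, collapse = ""),
       gc = rowMeans(matrix(bases %in% c("G", "C"), nrow = n)))
}

#' Initialize the simulation state
#'
#' Builds the RNA pool (i.i.d. bases under the configured GC bias), an
#' empty charge vector, and the seeded bridge peptides.
#'
#' @param cfg a `sim_config`.
#' @return a `bp_state`: list with `rna` (seq, gc), `charged` (amino acid
#'   or NA per RNA), `peptides` (list of residue vectors), `is_bp` logical.
#' @export
init_pool <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  rna <- .new_rna(cfg$n_rna, cfg)
  peptides <- rep(list(c("Arg", "Gly", "Gly", "Ala", "Asp")), cfg$bp_initial)
  structure(list(rna = rna,
                 charged = rep(NA_character_, cfg$n_rna),
                 incorporated = character(0),
                 peptides = peptides,
                 is_bp = vapply(peptides, is_bridge_peptide,
                                logical(1), motif = cfg$bp_motif,
                                min_length = cfg$bp_min_length)),
            class = "bp_state")
}

#' Aminoacylation step
#'
#' Charges every uncharged RNA: with probability
#' min(1, beta * n_bp / n_rna * gc_fraction) the molecule is Arg-charged
#' (BP-mediated, favoring GC-rich RNAs); otherwise an amino acid is drawn
#' from the chemical-code weights. With beta = 0 all charging is
#' chemical-code.
#'
#' @param state a `bp_state`.
#' @param cfg a `sim_config`.
#' @return the updated state.
#' @export
aminoacylate_step <- function(state, cfg) {
  free <- which(is.na(state$charged))
  if (!length(free)) return(state)
  n_bp <- sum(state$is_bp)
  q <- pmin(1, cfg$bp_bias * n_bp / length(state$charged) *
              state$rna$gc[free])
  bp_mediated <- stats::runif(length(free)) < q
  aa <- character(length(free))
  aa[bp_mediated] <- "Arg"
  n_chem <- sum(!bp_mediated)
  if (n_chem > 0L) {
    aa[!bp_mediated] <- sample(names(cfg$aa_weights), n_chem, replace = TRUE,
                               prob = cfg$aa_weights)
  }
  state$charged[free] <- aa
  state
}

#' Hybridization-dependent peptide formation step
#'
#' Charged RNAs are shuffled and partitioned into consecutive groups whose
#' sizes are drawn uniformly from the peptide length range; each group
#' yields one peptide (its carried residues in group order) and its RNAs
#' return uncharged to the pool. Leftover charged RNAs (fewer than the
#' minimum length) stay charged for the next cycle.
#'
#' @inheritParams aminoacylate_step
#' @return the updated state.
#' @export
hdp_step <- function(state, cfg) {
  charged <- which(!is.na(state$charged))
  lmin <- cfg$peptide_len_range[1]
  lmax <- cfg$peptide_len_range[2]
  if (length(charged) < max(2L, lmin)) return(state)
  idx <- sample(charged)
  new_peps <- list()
  while (length(idx) >= lmin) {
    L <- sample(seq.int(lmin, lmax), 1L)
    L <- min(L, length(idx))
    if (L < lmin) break
    grp <- idx[seq_len(L)]
    idx <- idx[-seq_len(L)]
    new_peps[[length(new_peps) + 1L]] <- state$charged[grp]
    state$charged[grp] <- NA_character_
  }
  if (length(new_peps)) {
    state$peptides <- c(state$peptides, new_peps)
    state$is_bp <- c(state$is_bp,
                     vapply(new_peps, is_bridge_peptide, logical(1),
                            motif = cfg$bp_motif,
                            min_length = cfg$bp_min_length))
    state$incorporated <- unlist(new_peps)
  }
  state
}

#' Degradation and replenishment step
#'
#' Peptides survive with probability `base_survival` (times
#' `survival_bonus` for bridge peptides, capped at 1). RNAs survive with
#' probability `base_survival + gc_slope * (gc_fraction - 0.5)` clamped to
#' [0, 1] — GC-rich molecules persist longer — and the pool is replenished
#' with freshly synthesized molecules back to `n_rna`.
#'
#' @inheritParams aminoacylate_step
#' @return the updated state; the RNA pool size is exactly `n_rna`.
#' @export
degrade_replenish_step <- function(state, cfg) {
  if (length(state$peptides)) {
    p_surv <- pmin(1, cfg$base_survival *
                     ifelse(state$is_bp, cfg$survival_bonus, 1))
    keep <- stats::runif(length(state$peptides)) < p_surv
    state$peptides <- state$peptides[keep]
    state$is_bp <- state$is_bp[keep]
  }
  p_rna <- pmin(1, pmax(0, cfg$base_survival +
                          cfg$gc_slope * (state$rna$gc - 0.5)))
  keep <- stats::runif(length(state$rna$gc)) < p_rna
  fresh <- .new_rna(cfg$n_rna - sum(keep), cfg)
  state$rna <- list(seq = c(state$rna$seq[keep], fresh$seq),
                    gc = c(state$rna$gc[keep], fresh$gc))
  state$charged <- c(state$charged[keep],
                     rep(NA_character_, length(fresh$gc)))
  state
}

# arg_fraction: share of Arg among residues incorporated into peptides this
# cycle (the chemical-code null applies to this quantity); pool_arg_fraction:
# share of Arg among residues of the surviving peptide pool, which is
# survival-biased toward bridge peptides.
.record <- function(state, cycle) {
  n_pep <- length(state$peptides)
  res <- unlist(state$peptides)
  inc <- state$incorporated
  data.frame(cycle = cycle,
             n_peptides = n_pep,
             n_bp = sum(state$is_bp),
             bp_fraction = if (n_pep) sum(state$is_bp) / n_pep else 0,
             arg_fraction = if (length(inc)) mean(inc == "Arg") else 0,
             pool_arg_fraction = if (length(res)) mean(res == "Arg") else 0,
             mean_gc = mean(state$rna$gc),
             pool_size = length(state$rna$gc))
}

#' Run the bridge-peptide world simulation
#'
#' Applies aminoacylation, HDP formation and degradation/replenishment for
#' `n_cycles` cycles and records one summary row per cycle (cycle 0 is the
#' initial state). Fully reproducible under `cfg$seed`.
#'
#' @param cfg a `sim_config`.
#' @return a `bp_trajectory`: data.frame with columns `cycle`,
#'   `n_peptides`, `n_bp`, `bp_fraction` (of the peptide pool),
#'   `arg_fraction` (of residues incorporated that cycle — the quantity the
#'   chemical-code null applies to), `pool_arg_fraction` (of residues in
#'   the surviving peptide pool, survival-biased toward bridge peptides),
#'   `mean_gc`, `pool_size`; the configuration is attached as attribute
#'   `config`.
#' @examples
#' traj <- run_simulation(sim_config(n_rna = 100, n_cycles = 5, seed = 1))
#' tail(traj, 2)
#' @export
run_simulation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  state <- init_pool(cfg)
  rows <- vector("list", cfg$n_cycles + 1L)
  rows[[1L]] <- .record(state, 0L)
  for (cy in seq_len(cfg$n_cycles)) {
    state$incorporated <- character(0)
    state <- aminoacylate_step(state, cfg)
    state <- hdp_step(state, cfg)
    state <- degrade_replenish_step(state, cfg)
    rows[[cy + 1L]] <- .record(state, cy)
  }
  traj <- do.call(rbind, rows)
  attr(traj, "config") <- cfg
  class(traj) <- c("bp_trajectory", "data.frame")
  traj
}

#' Plot a simulation trajectory
#'
#' Base-graphics view of the bridge-peptide and Arg fractions over cycles.
#'
#' @param x a `bp_trajectory`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.bp_trajectory <- function(x, ...) {
  graphics::plot(x$cycle, x$bp_fraction, type = "l", ylim = c(0, 1),
                 xlab = "cycle", ylab = "fraction", ...)
  graphics::lines(x$cycle, x$arg_fraction, lty = 2)
  graphics::legend("topleft", legend = c("BP fraction", "Arg fraction"),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}
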