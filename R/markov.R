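# Exact single-locus Markov chain for tiny censuses: the brute-force
# validation oracle for the simulator.
#
# The chain mirrors the lifecycle's reproduction scheme exactly in
# distribution: parents of each offspring are drawn independently with
# probability proportional to fitness within each sex, gametes unite at
# random, and a heterozygous parent transmits either allele with probability
# 1/2.  Allele counts alone are not Markov (the split of female copies into
# heterozygotes and homozygotes affects fitness-weighted transmission), so
# the state is genotype-resolved: female genotype counts (n0, n1, n2) for
# 0/1/2 mutant copies, together with the male carrier count (haplodiploid,
# males are haploid) or male genotype counts (diploid).  Offspring genotype
# counts are then multinomial given the two transmission probabilities,
# which makes the one-generation transition exact.

genotype_compositions <- function(N) {
  out <- list()
  for (n2 in 0:N) for (n1 in 0:(N - n2))
    out[[length(out) + 1L]] <- c(N - n1 - n2, n1, n2)
  do.call(rbind, out)
}

dmultinom3 <- function(counts_matrix, size, prob) {
  # probability of each row of (n0, n1, n2) under Multinomial(size, prob)
  apply(counts_matrix, 1L, function(n) stats::dmultinom(n, size, prob))
}

#' Build the exact single-locus transition chain
#'
#' Constructs the one-generation transition matrix over genotype-resolved
#' allele states for a single mutation with selection coefficient `s` and
#' dominance `h`, for small censuses.  Genotype fitnesses are `1`,
#' `1 + s * h`, `1 + s` in females (and diploid males) and `1`,
#' `1 + s * h_haploid` in haploid males.
#'
#' @param mode `"haplodiploid"` or `"diploid"`.
#' @param Nm,Nf Census sizes (small; the state space is
#'   `C(Nf+2, 2) * (Nm + 1)` for haplodiploid and `C(Nf+2, 2) * C(Nm+2, 2)`
#'   for diploid states).
#' @param s,h Selection and dominance coefficients.
#' @param h_haploid Haploid dominance coefficient (default 1).
#' @param max_states Refuse to build chains larger than this (default 2e4).
#' @return An object of class `hd_chain`: list with the transition matrix
#'   `P`, the state table `states` (columns `f0`, `f1`, `f2` and `m0`, `m1`
#'   and, for diploid, `m2`), and the indices of the two absorbing states
#'   `idx_lost` and `idx_fixed`.
#' @examples
#' ch <- hd_markov_chain("haplodiploid", Nm = 2, Nf = 2, s = 0, h = 0)
#' hd_fixation_probability(ch, "single_copy_female")  # 1/6
#' @export
hd_markov_chain <- function(mode = c("haplodiploid", "diploid"),
                            Nm, Nf, s, h, h_haploid = 1,
                            max_states = 20000) {
  mode <- match.arg(mode)
  stopifnot(Nm >= 1, Nf >= 1)
  hap <- mode == "haplodiploid"
  fcomp <- genotype_compositions(Nf)
  mcomp <- if (hap) matrix(c(Nm:0, 0:Nm), ncol = 2,
                           dimnames = NULL) else genotype_compositions(Nm)
  nF <- nrow(fcomp); nM <- nrow(mcomp)
  S <- nF * nM
  if (S > max_states)
    stop(sprintf("state space too large: %d states (max_states = %d)", S, max_states))

  wF <- pmax(c(1, 1 + s * h, 1 + s), 0)
  tF <- c(0, 0.5, 1)
  wMhap <- pmax(c(1, 1 + s * h_haploid), 0)

  # state index: female composition varies fastest
  idx <- function(fi, mi) (mi - 1L) * nF + fi
  P <- matrix(0, S, S)
  for (mi in seq_len(nM)) {
    m <- mcomp[mi, ]
    pm <- if (hap) {
      d <- m[1] * wMhap[1] + m[2] * wMhap[2]
      if (d > 0) m[2] * wMhap[2] / d else 0
    } else {
      d <- sum(m * wF)
      if (d > 0) sum(m * wF * tF) / d else 0
    }
    for (fi in seq_len(nF)) {
      f <- fcomp[fi, ]
      dF <- sum(f * wF)
      pf <- if (dF > 0) sum(f * wF * tF) / dF else 0
      q <- c((1 - pf) * (1 - pm), pf * (1 - pm) + (1 - pf) * pm, pf * pm)
      fdist <- dmultinom3(fcomp, Nf, q)      # daughters: random union
      mdist <- if (hap) stats::dbinom(mcomp[, 2], Nm, pf)  # sons: maternal gamete
               else dmultinom3(mcomp, Nm, q)
      P[idx(fi, mi), ] <- as.vector(outer(fdist, mdist))
    }
  }
  f_lost <- which(fcomp[, 2] == 0 & fcomp[, 3] == 0)
  f_fixed <- which(fcomp[, 3] == Nf)
  m_lost <- if (hap) which(mcomp[, 2] == 0) else which(mcomp[, 2] == 0 & mcomp[, 3] == 0)
  m_fixed <- if (hap) which(mcomp[, 2] == Nm) else which(mcomp[, 3] == Nm)
  states <- cbind(fcomp[rep(seq_len(nF), nM), , drop = FALSE],
                  mcomp[rep(seq_len(nM), each = nF), , drop = FALSE])
  colnames(states) <- c("f0", "f1", "f2",
                        if (hap) c("m0", "m1") else c("m0", "m1", "m2"))
  structure(list(mode = mode, Nm = Nm, Nf = Nf, s = s, h = h,
                 h_haploid = h_haploid, P = P, states = states,
                 fcomp = fcomp, mcomp = mcomp, nF = nF, nM = nM,
                 idx_lost = idx(f_lost, m_lost),
                 idx_fixed = idx(f_fixed, m_fixed)),
            class = "hd_chain")
}

state_index <- function(chain, females, males) {
  fi <- which(apply(chain$fcomp, 1L, function(x) all(x == females)))
  mv <- if (chain$mode == "haplodiploid") c(chain$Nm - males, males) else males
  mi <- which(apply(chain$mcomp, 1L, function(x) all(x == mv)))
  if (!length(fi) || !length(mi)) stop("invalid initial state")
  (mi - 1L) * chain$nF + fi
}

#' Exact fixation probability from the chain
#'
#' Absorption probability into the all-copies state, by direct linear solve
#' of the transient system.  For a single neutral copy this equals the
#' reproductive-value weight of the carrying genome: `1/(3N)` in a
#' haplodiploid population with `Nm = Nf = N` (whether the copy starts in a
#' female or a male genome) and `1/(4N)` in the matched diploid population.
#'
#' @param chain An `hd_chain` from [hd_markov_chain()].
#' @param initial `"single_copy_female"` (one heterozygous female),
#'   `"single_copy_male"` (one carrier male: hemizygous if haplodiploid,
#'   heterozygous if diploid), or a list with elements `females = c(n0, n1,
#'   n2)` and `males` (carrier count for haplodiploid, `c(n0, n1, n2)` for
#'   diploid).
#' @return Fixation probability in `[0, 1]`.
#' @export
hd_fixation_probability <- function(chain, initial = "single_copy_female") {
  stopifnot(inherits(chain, "hd_chain"))
  Nf <- chain$Nf; Nm <- chain$Nm
  if (is.character(initial)) {
    initial <- match.arg(initial, c("single_copy_female", "single_copy_male"))
    init <- if (initial == "single_copy_female") {
      list(females = c(Nf - 1, 1, 0),
           males = if (chain$mode == "haplodiploid") 0 else c(Nm, 0, 0))
    } else {
      list(females = c(Nf, 0, 0),
           males = if (chain$mode == "haplodiploid") 1 else c(Nm - 1, 1, 0))
    }
  } else init <- initial
  i0 <- state_index(chain, init$females, init$males)
  if (i0 == chain$idx_fixed) return(1)
  if (i0 == chain$idx_lost) return(0)
  S <- nrow(chain$P)
  absorbing <- c(chain$idx_lost, chain$idx_fixed)
  trans <- setdiff(seq_len(S), absorbing)
  Q <- chain$P[trans, trans, drop = FALSE]
  b <- chain$P[trans, chain$idx_fixed]
  u <- solve(diag(length(trans)) - Q, b)
  unname(u[match(i0, trans)])
}

#' Exact fixation probabilities over a parameter grid
#'
#' Tabulates [hd_fixation_probability()] for every combination of mode,
#' selection coefficient, dominance coefficient and initial placement
#' (single copy in a female genome and in a male genome).
#'
#' @param Nm,Nf Census sizes.
#' @param s_values,h_values Numeric grids.
#' @param modes Modes to include.
#' @param h_haploid Haploid dominance coefficient.
#' @return A data frame with columns `mode`, `Nm`, `Nf`, `s`, `h`,
#'   `placement`, `fixation_probability`.
#' @export
hd_oracle_table <- function(Nm, Nf, s_values = c(-0.05, 0, 0.05),
                            h_values = c(0, 1),
                            modes = c("haplodiploid", "diploid"),
                            h_haploid = 1) {
  rows <- list()
  for (mode in modes) for (s in s_values) for (h in h_values) {
    ch <- hd_markov_chain(mode, Nm, Nf, s, h, h_haploid)
    for (pl in c("female", "male")) {
      rows[[length(rows) + 1L]] <- data.frame(
        mode = mode, Nm = Nm, Nf = Nf, s = s, h = h, placement = pl,
        fixation_probability = hd_fixation_probability(
          ch, paste0("single_copy_", pl)))
    }
  }
  do.call(rbind, rows)
}

#' Empirical fixation frequency from simulator replicates
#'
#' Runs the compiled simulation engine repeatedly at a single locus with
#' `mu = 0`, starting from one mutant copy, and counts how often the copy
#' fixes.  Used to validate the simulator against the exact chain.
#'
#' @param mode,Nm,Nf,s,h,h_haploid As in [hd_config()].
#' @param n_rep Number of replicates.
#' @param placement `"female"` or `"male"`: genome carrying the initial copy.
#' @param max_generations Per-replicate cap (absorption is certain long
#'   before this at the small censuses this is meant for).
#' @param seed Optional seed (`set.seed` is called if given).
#' @return List with `n_fixed`, `n_rep`, `proportion`, `n_unresolved`.
#' @export
hd_fixation_replicates <- function(mode = c("haplodiploid", "diploid"),
                                   Nm, Nf, s, h, h_haploid = 1,
                                   n_rep = 1000L,
                                   placement = c("female", "male"),
                                   max_generations = 100000L,
                                   seed = NULL) {
  mode <- match.arg(mode)
  placement <- match.arg(placement)
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_fixation_replicates(mode == "haplodiploid", Nm, Nf, s, h,
                                 h_haploid, as.integer(n_rep),
                                 if (placement == "female") 1L else 2L,
                                 as.integer(max_generations))
  if (res[2L] > 0L)
    warning(sprintf("%d replicates unresolved after %d generations",
                    res[2L], max_generations))
  list(n_fixed = res[1L], n_rep = as.integer(n_rep),
       proportion = res[1L] / n_rep, n_unresolved = res[2L])
}
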