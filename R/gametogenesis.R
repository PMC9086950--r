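# Meiosis: crossover recombination and de novo mutation.
#
# The crossover process is the standard flat genetic map implied by a single
# per-adjacent-locus-pair rate r: a Poisson(r * (L - 1)) number of
# breakpoints at distinct uniform integer positions in [1, L), no
# interference.  Haploid males do not recombine: a father transmits a clonal
# copy of his single genome (then mutated).  De novo mutation applies to
# every transmitted gamete; each event creates a fresh mutation record
# (infinite-alleles per event, so two records may share a position).

#' Draw crossover breakpoints for one meiosis
#'
#' @param L Genome length in loci.
#' @param r Per-adjacent-locus-pair recombination rate.
#' @return A sorted, duplicate-free integer vector of breakpoint positions in
#'   `[1, L)`; empty when no crossover occurs (always so when the rate is 0).
#' @examples
#' set.seed(1)
#' hd_draw_crossovers(1e6, 1e-6)
#' @export
hd_draw_crossovers <- function(L, r) {
  stopifnot(L >= 1, r >= 0)
  if (r <= 0 || L < 2) return(integer(0))
  n <- stats::rpois(1L, r * (L - 1))
  if (n == 0L) return(integer(0))
  if (n > L - 1) stop("more crossovers drawn than available breakpoint positions")
  # uniform distinct positions (equivalent to re-drawing duplicates)
  sort(sample.int(L - 1, n))
}

#' Recombine two genomes into one gamete
#'
#' Splits the genome into half-open segments `[prev_bp, bp)` at the given
#' breakpoints and takes, for each segment, the mutations of the alternating
#' strand beginning with `start`.  Segment membership is by mutation
#' position.
#'
#' @param genome_a,genome_b Non-null genomes (integer vectors of mutation
#'   ids) of one parent.
#' @param breakpoints Sorted integer breakpoint positions (see
#'   [hd_draw_crossovers()]).
#' @param start Strand carrying the first segment, `"a"` or `"b"`.
#' @param registry Mutation registry used to look up positions.
#' @return The gamete: an integer vector of mutation ids sorted by
#'   (position, id).
#' @examples
#' reg <- data.frame(id = 1:3, position = c(10L, 500L, 300L),
#'                   s = 0, h = 0, origin = 0L, count = 1L)
#' hd_recombine(c(1L, 2L), 3L, breakpoints = 200L, start = "a", registry = reg)
#' @export
hd_recombine <- function(genome_a, genome_b, breakpoints, start = c("a", "b"),
                         registry) {
  start <- match.arg(start)
  if (is_null_genome(genome_a) || is_null_genome(genome_b))
    stop("cannot recombine a null genome; haploid transmission must use hd_copy_genome()")
  stopifnot(!is.unsorted(breakpoints))
  pick <- function(g, want_even) {
    if (!length(g)) return(g)
    pos <- registry$position[match(g, registry$id)]
    seg <- findInterval(pos, breakpoints)  # number of breakpoints <= pos
    g[(seg %% 2L == 0L) == want_even]
  }
  a_first <- start == "a"
  out <- c(pick(genome_a, a_first), pick(genome_b, !a_first))
  sort_genome_ids(out, registry)
}

#' Clonal transmission of a haploid father's genome
#'
#' Haploid males carry one real genome and one null genome; recombination
#' with a null genome is undefined, so paternal transmission is clonal (the
#' copy is subsequently subject to de novo mutation like any gamete).
#'
#' @param genome A non-null genome.
#' @return An exact copy.
#' @export
hd_copy_genome <- function(genome) {
  if (is_null_genome(genome))
    stop("cannot copy a null genome")
  genome
}

#' Draw de novo mutations for one gamete
#'
#' The count is `Poisson(mu * L)`; positions are uniform on `[0, L)`.  Each
#' new mutation is a fresh record with its own id and the run's treatment
#' `(s, h)`; the haploid dominance coefficient is carried alongside.
#'
#' @param L,mu Genome length and per-locus mutation rate.
#' @param s,h Selection and dominance coefficient of the treatment.
#' @param generation Origin generation recorded for the new mutations.
#' @param next_id First id to assign.
#' @param h_haploid Haploid dominance coefficient (default 1).
#' @return A data frame of new mutation records (possibly 0 rows) with
#'   columns `id`, `position`, `s`, `h`, `h_haploid`, `origin`.
#' @export
hd_draw_new_mutations <- function(L, mu, s, h, generation, next_id,
                                  h_haploid = 1) {
  stopifnot(L >= 1, mu >= 0)
  n <- if (mu > 0) stats::rpois(1L, mu * L) else 0L
  pos <- if (n > 0L) as.integer(floor(stats::runif(n) * L)) else integer(0)
  pos[pos >= L] <- as.integer(L - 1)
  data.frame(id = seq_len(n) + next_id - 1L, position = pos,
             s = rep(s, n), h = rep(h, n), h_haploid = rep(h_haploid, n),
             origin = rep(as.integer(generation), n))
}
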