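# Genotype-to-fitness map.  Fitness acts as reproduction success: parents of
# each offspring are drawn with probability proportional to fitness, within
# each sex.  Factors combine multiplicatively across mutations; a
# mutation-free individual has fitness exactly 1, and negative products are
# clamped at 0 (only reachable for s < -1).

#' Fitness factor of one mutation in one genotype
#'
#' Hemizygous carriers (haploid males) express the haploid dominance
#' coefficient, fixed at 1 in all standard treatments, so a male carrier has
#' factor `1 + s`.  Heterozygotes have `1 + s * h`; homozygotes `1 + s`.
#'
#' @param s Selection coefficient.
#' @param h Dominance coefficient.
#' @param zygosity `"hemizygous"`, `"heterozygous"` or `"homozygous"`.
#' @param h_haploid Haploid dominance coefficient (default 1).
#' @return The multiplicative fitness factor.
#' @examples
#' hd_genotype_factor(0.001, h = 0, "hemizygous")    # 1.001: fully exposed
#' hd_genotype_factor(-0.01, h = 0, "heterozygous")  # 1: masked
#' @export
hd_genotype_factor <- function(s, h, zygosity = c("hemizygous", "heterozygous",
                                                  "homozygous"),
                               h_haploid = 1) {
  zygosity <- match.arg(zygosity)
  switch(zygosity,
         hemizygous = 1 + s * h_haploid,
         heterozygous = 1 + s * h,
         homozygous = 1 + s)
}

#' Fitness of one individual
#'
#' The product of [hd_genotype_factor()] over all mutation ids the individual
#' carries.  Zygosity is per id: present in both genomes is homozygous,
#' present in one of two non-null genomes is heterozygous, and present in the
#' sole non-null genome of a haploid male is hemizygous.  Two distinct
#' mutations at the same position never form a homozygote.
#'
#' @param individual An individual (list with `sex` and two genome slots).
#' @param registry Mutation registry supplying per-id `s` and `h`.
#' @param h_haploid Haploid dominance coefficient (default 1).
#' @return Non-negative fitness; 1 for a mutation-free individual.
#' @export
hd_individual_fitness <- function(individual, registry, h_haploid = 1) {
  g1 <- individual$genomes[[1L]]
  g2 <- individual$genomes[[2L]]
  n1 <- is_null_genome(g1); n2 <- is_null_genome(g2)
  if (n1 && n2) return(1)
  if (xor(n1, n2)) {
    ids <- if (n1) g2 else g1
    if (!length(ids)) return(1)
    s <- registry$s[match(ids, registry$id)]
    w <- prod(1 + s * h_haploid)
  } else {
    hom <- intersect(g1, g2)
    het <- setdiff(c(g1, g2), hom)
    w <- 1
    if (length(hom)) w <- w * prod(1 + registry$s[match(hom, registry$id)])
    if (length(het)) {
      i <- match(het, registry$id)
      w <- w * prod(1 + registry$s[i] * registry$h[i])
    }
  }
  max(w, 0)
}
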