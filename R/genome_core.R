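# Core domain types: mutations, genomes, individuals, populations.
#
# A genome is an integer vector of mutation ids, kept sorted by
# (position, id); a null genome (the empty second chromosome set of a haploid
# male) is NULL.  An individual is a list with a sex and exactly two genome
# slots.  The registry is a data frame with one row per segregating mutation:
# id, position, s, h, origin, count.  Ids are assigned sequentially from 1 in
# creation order and are unique within a run.

is_null_genome <- function(g) is.null(g)

new_individual <- function(sex, g1, g2) {
  list(sex = sex, genomes = list(g1, g2))
}

empty_registry <- function() {
  data.frame(id = integer(0), position = integer(0), s = numeric(0),
             h = numeric(0), origin = integer(0), count = integer(0))
}

empty_substitution_log <- function() {
  data.frame(id = integer(0), position = integer(0), s = numeric(0),
             h = numeric(0), origin_generation = integer(0),
             fixation_generation = integer(0))
}

# sort mutation ids by (position, id); positions looked up in `registry`
sort_genome_ids <- function(ids, registry) {
  if (length(ids) < 2L) return(ids)
  pos <- registry$position[match(ids, registry$id)]
  ids[order(pos, ids)]
}

#' Create a mutation-free population
#'
#' Initializes a population of `Nm` males and `Nf` females with empty
#' genomes, in the inheritance mode given by the configuration.  In
#' haplodiploid mode every male has one real (empty) genome and one null
#' genome; in diploid mode all individuals have two real genomes.
#'
#' @param config An [hd_config()] object.
#' @return An object of class `hd_population`.
#' @examples
#' pop <- hd_population(hd_config("haplodiploid", Nm = 10, Nf = 10))
#' hd_census(pop)
#' @export
hd_population <- function(config) {
  stopifnot(inherits(config, "hd_config"))
  females <- replicate(config$Nf,
                       new_individual("female", integer(0), integer(0)),
                       simplify = FALSE)
  males <- if (config$mode == "haplodiploid") {
    replicate(config$Nm, new_individual("male", integer(0), NULL),
              simplify = FALSE)
  } else {
    replicate(config$Nm, new_individual("male", integer(0), integer(0)),
              simplify = FALSE)
  }
  structure(list(mode = config$mode,
                 generation = 0L,
                 params = config,
                 females = females,
                 males = males,
                 registry = empty_registry(),
                 next_id = 1L,
                 substitution_log = empty_substitution_log(),
                 n_lost = 0,
                 n_created = 0),
            class = "hd_population")
}

#' @export
print.hd_population <- function(x, ...) {
  cs <- hd_census(x)
  cat(sprintf("<hd_population> %s, generation %d: %d males + %d females (%d genome copies), %d segregating mutations\n",
              x$mode, x$generation, length(x$males), length(x$females),
              cs$n_genome_copies, nrow(x$registry)))
  invisible(x)
}

all_genomes <- function(pop) {
  c(unlist(lapply(pop$females, `[[`, "genomes"), recursive = FALSE),
    unlist(lapply(pop$males, `[[`, "genomes"), recursive = FALSE))
}

#' Census of a population
#'
#' Counts individuals and non-null genome copies, and the expected number of
#' new mutations entering the population per generation,
#' `n_genome_copies * mu * L`.  With a 1:1 sex ratio (`Nm = Nf = N`) a
#' haplodiploid population carries `3N` genome copies (1.5 per individual)
#' against `4N` in a diploid population -- the chromosome-accounting
#' difference that reduces the mutation influx of haplodiploids from `2N mu`
#' to `1.5N mu` per locus.
#'
#' @param pop An `hd_population`.
#' @return A list of class `hd_census` with elements `n_individuals`,
#'   `n_genome_copies` and `expected_mutation_influx`.
#' @export
hd_census <- function(pop) {
  stopifnot(inherits(pop, "hd_population"))
  bad <- validate_individual_structure(pop)
  if (length(bad)) stop("malformed population: ", bad[[1L]])
  genomes <- all_genomes(pop)
  ncopies <- sum(!vapply(genomes, is_null_genome, logical(1)))
  structure(list(n_individuals = length(pop$females) + length(pop$males),
                 n_genome_copies = ncopies,
                 expected_mutation_influx = ncopies * pop$params$mu * pop$params$L),
            class = "hd_census")
}

#' @export
print.hd_census <- function(x, ...) {
  cat(sprintf("individuals: %d; genome copies: %d; expected mutation influx/generation: %g\n",
              x$n_individuals, x$n_genome_copies, x$expected_mutation_influx))
  invisible(x)
}

validate_individual_structure <- function(pop) {
  out <- character(0)
  chk <- function(inds, sex) {
    for (i in seq_along(inds)) {
      ind <- inds[[i]]
      who <- sprintf("%s %d", sex, i)
      if (length(ind$genomes) != 2L) {
        out <<- c(out, sprintf("%s: does not have exactly 2 genome slots", who))
        next
      }
      nn <- sum(!vapply(ind$genomes, is_null_genome, logical(1)))
      if (pop$mode == "haplodiploid" && sex == "male" && nn != 1L)
        out <<- c(out, sprintf("%s: haplodiploid male must have exactly one non-null genome (has %d)", who, nn))
      if (pop$mode == "haplodiploid" && sex == "female" && nn != 2L)
        out <<- c(out, sprintf("%s: haplodiploid female must have two non-null genomes (has %d)", who, nn))
      if (pop$mode == "diploid" && nn != 2L)
        out <<- c(out, sprintf("%s: diploid individual must have two non-null genomes (has %d)", who, nn))
    }
  }
  chk(pop$females, "female")
  chk(pop$males, "male")
  out
}

#' Validate population invariants
#'
#' Reports (never raises) violations of the structural invariants: genome
#' slot counts and null-genome placement for the inheritance mode, genome
#' sorting and duplicate-freedom, mutation positions within `[0, L)`, and
#' agreement of every registry copy count with a brute-force recount over all
#' non-null genomes.
#'
#' @param pop An `hd_population`.
#' @return A character vector of violations; empty if all invariants hold.
#' @export
hd_validate <- function(pop) {
  stopifnot(inherits(pop, "hd_population"))
  out <- validate_individual_structure(pop)
  reg <- pop$registry
  if (anyDuplicated(reg$id))
    out <- c(out, "registry: duplicated mutation ids")
  if (nrow(reg) && (any(reg$position < 0) || any(reg$position >= pop$params$L)))
    out <- c(out, "registry: mutation position outside [0, L)")
  genomes <- all_genomes(pop)
  labels <- c(sprintf("female %d genome %d", rep(seq_along(pop$females), each = 2), 1:2),
              sprintf("male %d genome %d", rep(seq_along(pop$males), each = 2), 1:2))
  for (k in seq_along(genomes)) {
    g <- genomes[[k]]
    if (is_null_genome(g)) next
    if (anyDuplicated(g))
      out <- c(out, sprintf("%s: duplicated mutation ids", labels[[k]]))
    if (!all(g %in% reg$id)) {
      out <- c(out, sprintf("%s: carries ids missing from the registry", labels[[k]]))
      next
    }
    if (!identical(g, sort_genome_ids(g, reg)))
      out <- c(out, sprintf("%s: not sorted by (position, id)", labels[[k]]))
  }
  # copy-count conservation: full recount
  carried <- unlist(genomes, use.names = FALSE)
  for (i in seq_len(nrow(reg))) {
    n <- sum(carried == reg$id[i])
    if (n != reg$count[i])
      out <- c(out, sprintf("mutation %d: registry count %d but recount %d",
                            reg$id[i], reg$count[i], n))
  }
  out
}
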