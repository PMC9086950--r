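# Fixation/loss bookkeeping and per-generation time series output.

#' Classify fixed and lost mutations and purge them
#'
#' A mutation is fixed iff its copy count equals the number of non-null
#' genome copies in the population (haplodiploid: present twice in every
#' female and once in every male); it is lost iff its copy count is 0.
#' Fixed mutations are removed from all genomes and appended to the
#' substitution log with the current generation as fixation generation; lost
#' mutations are purged silently.  Removing a fixed mutation multiplies
#' every individual's fitness within a sex by the same factor, so
#' fitness-proportional parent sampling is unaffected.
#'
#' @param pop An `hd_population` with current copy counts.
#' @return A list with `population` (purged), `n_fixed` and `n_lost`.
#' @export
hd_classify_and_purge <- function(pop) {
  stopifnot(inherits(pop, "hd_population"))
  reg <- pop$registry
  ncopies <- hd_census(pop)$n_genome_copies
  if (any(reg$count > ncopies))
    stop("internal consistency error: copy count exceeds number of genome copies")
  fixed <- reg$count == ncopies & ncopies > 0L
  lost <- reg$count == 0L
  n_fixed <- sum(fixed); n_lost <- sum(lost)
  if (n_fixed) {
    fixed_ids <- reg$id[fixed]
    strip <- function(ind) {
      ind$genomes <- lapply(ind$genomes, function(g)
        if (is_null_genome(g)) g else g[!(g %in% fixed_ids)])
      ind
    }
    pop$females <- lapply(pop$females, strip)
    pop$males <- lapply(pop$males, strip)
    pop$substitution_log <- rbind(
      pop$substitution_log,
      data.frame(id = reg$id[fixed], position = reg$position[fixed],
                 s = reg$s[fixed], h = reg$h[fixed],
                 origin_generation = reg$origin[fixed],
                 fixation_generation = rep(pop$generation, n_fixed)))
  }
  pop$registry <- reg[!fixed & !lost, , drop = FALSE]
  rownames(pop$registry) <- NULL
  pop$n_lost <- pop$n_lost + n_lost
  list(population = pop, n_fixed = n_fixed, n_lost = n_lost)
}

#' Summarize a simulation result
#'
#' @param result An `hd_result` from [hd_simulate()].
#' @param window `"recorded"` (generations after the burn-in; the default)
#'   or `"all"`.  A fixation is attributed to the generation in which the
#'   copy count first reaches the census, so mutations arising during the
#'   burn-in but fixing afterwards count in the recorded window.
#' @return A one-row data frame: `window`, `generations`, `total_fixations`,
#'   `fixations_per_generation`, `final_segregating`.
#' @export
hd_summarize <- function(result, window = c("recorded", "all")) {
  stopifnot(inherits(result, "hd_result"))
  window <- match.arg(window)
  pg <- result$per_generation
  keep <- if (window == "recorded") pg$generation > result$config$burn_in else rep(TRUE, nrow(pg))
  if (!any(keep)) stop("empty summary window")
  n <- sum(keep)
  tot <- sum(pg$substitutions[keep])
  data.frame(window = window, generations = n, total_fixations = tot,
             fixations_per_generation = tot / n,
             final_segregating = pg$segregating[nrow(pg)])
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write the per-generation time series as TSV
#'
#' One row per generation; columns `generation`, `substitutions`,
#' `cumulative_substitutions`, `segregating`, `mean_fitness_females`,
#' `mean_fitness_males`.  Identical `(config, seed)` runs produce
#' byte-identical files.
#'
#' @param result An `hd_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
hd_write_timeseries <- function(result, path) {
  stopifnot(inherits(result, "hd_result"))
  write_tsv(result$per_generation, path)
}

#' Write the substitution log as TSV
#'
#' One row per fixed mutation; columns `id`, `position`, `s`, `h`,
#' `origin_generation`, `fixation_generation`.
#'
#' @inheritParams hd_write_timeseries
#' @return `path`, invisibly.
#' @export
hd_write_substitution_log <- function(result, path) {
  stopifnot(inherits(result, "hd_result"))
  write_tsv(result$substitution_log, path)
}
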