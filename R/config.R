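#' Simulation configuration
#'
#' Bundles every parameter of one simulation run.  Defaults are the standard
#' study conditions used throughout the package's experiments: populations of
#' 1,000 males and 1,000 females, genomes of 10^6 loci, a per-locus mutation
#' rate of 10^-8, a per-adjacent-locus recombination rate of 10^-6, a haploid
#' dominance coefficient of 1, and 35,000 recorded generations after a
#' burn-in of 15,000 generations.
#'
#' @param mode `"haplodiploid"` (haploid males, diploid females) or
#'   `"diploid"`.
#' @param Nm,Nf Number of males and females in the fixed census (>= 1 each).
#' @param L Genome length in loci; positions are 0-based integers in
#'   `[0, L)`.
#' @param mu Per-locus, per-generation mutation rate (>= 0); every transmitted
#'   gamete receives `Poisson(mu * L)` new mutations at uniform positions.
#' @param r Per-adjacent-locus-pair recombination rate (>= 0); each meiosis
#'   draws `Poisson(r * (L - 1))` crossover breakpoints.
#' @param s Selection coefficient of new mutations (one mutation type per
#'   run); homozygous and hemizygous carriers have fitness factor `1 + s`.
#'   The simulation engine requires `s > -1`.
#' @param h Dominance coefficient in diploid genotypes: heterozygote factor
#'   `1 + s * h`.
#' @param h_haploid Haploid dominance coefficient: hemizygous (haploid male)
#'   factor `1 + s * h_haploid`.  Fixed at 1 in all standard treatments.
#' @param burn_in Generations run before the recorded window (>= 0); excluded
#'   from reported fixation statistics.
#' @param run_generations Recorded generations (>= 1).
#' @param seed Integer seed; a run is fully reproducible from
#'   `(config, seed)`.
#'
#' @return An object of class `hd_config`.
#' @examples
#' cfg <- hd_config("haplodiploid", Nm = 50, Nf = 50,
#'                  burn_in = 100, run_generations = 200, seed = 1)
#' @export
hd_config <- function(mode = c("haplodiploid", "diploid"),
                      Nm = 1000L, Nf = 1000L,
                      L = 1e6, mu = 1e-8, r = 1e-6,
                      s = 0, h = 0, h_haploid = 1,
                      burn_in = 15000L, run_generations = 35000L,
                      seed = 1L) {
  mode <- match.arg(mode)
  Nm <- as.integer(Nm); Nf <- as.integer(Nf)
  stopifnot(Nm >= 1L, Nf >= 1L, L >= 1, mu >= 0, r >= 0,
            burn_in >= 0L, run_generations >= 1L,
            is.finite(s), is.finite(h), is.finite(h_haploid))
  structure(list(mode = mode, Nm = Nm, Nf = Nf,
                 L = as.numeric(L), mu = mu, r = r,
                 s = s, h = h, h_haploid = h_haploid,
                 burn_in = as.integer(burn_in),
                 run_generations = as.integer(run_generations),
                 seed = as.integer(seed)),
            class = "hd_config")
}

#' @export
print.hd_config <- function(x, ...) {
  cat(sprintf("<hd_config> %s: Nm=%d Nf=%d L=%g mu=%g r=%g s=%g h=%g h_hap=%g\n",
              x$mode, x$Nm, x$Nf, x$L, x$mu, x$r, x$s, x$h, x$h_haploid))
  cat(sprintf("  burn_in=%d run_generations=%d seed=%d\n",
              x$burn_in, x$run_generations, x$seed))
  invisible(x)
}

#' Write a configuration to a YAML file
#'
#' Used to echo the exact configuration into every output directory so runs
#' can be reproduced from their artifacts alone.
#'
#' @param config An [hd_config()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
hd_write_config <- function(config, path) {
  stopifnot(inherits(config, "hd_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a configuration from a YAML file
#'
#' @param path YAML file written by [hd_write_config()] (or hand-written with
#'   the same field names).
#' @return An [hd_config()] object.
#' @export
hd_read_config <- function(path) {
  v <- yaml::read_yaml(path)
  do.call(hd_config, v)
}
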