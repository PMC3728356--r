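#' Single-locus autosomal dominant disease model
#'
#' Parameterises the disease locus used throughout the linkage engine: the
#' population frequency `q` of the disease allele D, and the penetrance
#' vector (probability of being affected) for the three genotypes DD, Dd and
#' dd.  The defaults encode a fully dominant model with 90% penetrance for
#' carriers, a disease allele frequency of 1e-4, and no phenocopies
#' (`f_dd = 0`), the standard assumption set for a rare dominant trait.
#'
#' @param disease_allele_freq probability `q` of the disease allele.
#' @param penetrance numeric triple `(f_DD, f_Dd, f_dd)` of affection
#'   probabilities given genotype.
#' @return object of class `disease_model`.
#' @examples
#' dm <- disease_model()
#' penetrance_prob(dm, "Dd", "affected")   # 0.9
#' founder_genotype_prior(dm)              # Hardy-Weinberg prior
#' @export
disease_model <- function(disease_allele_freq = 1e-4,
                          penetrance = c(0.9, 0.9, 0)) {
  q <- disease_allele_freq
  stopifnot(length(q) == 1L, q >= 0, q <= 1,
            length(penetrance) == 3L,
            all(penetrance >= 0), all(penetrance <= 1))
  structure(list(disease_allele_freq = as.numeric(q),
                 penetrance = setNames(as.numeric(penetrance),
                                       c("DD", "Dd", "dd"))),
            class = "disease_model")
}

#' @export
print.disease_model <- function(x, ...) {
  cat(sprintf("Single-locus disease model: q = %g, penetrance DD/Dd/dd = %g/%g/%g\n",
              x$disease_allele_freq, x$penetrance["DD"], x$penetrance["Dd"],
              x$penetrance["dd"]))
  invisible(x)
}

#' Penetrance probability P(phenotype | genotype)
#'
#' An unknown phenotype is uninformative and returns 1 for every genotype.
#'
#' @param model a [disease_model()].
#' @param genotype `"DD"`, `"Dd"` or `"dd"` (vectorised).
#' @param phenotype `"affected"`, `"unaffected"` or `"unknown"` (vectorised,
#'   recycled against `genotype`).
#' @return numeric vector of probabilities.
#' @export
penetrance_prob <- function(model, genotype, phenotype) {
  stopifnot(inherits(model, "disease_model"))
  stopifnot(all(genotype %in% c("DD", "Dd", "dd")),
            all(phenotype %in% c("affected", "unaffected", "unknown")))
  n <- max(length(genotype), length(phenotype))
  genotype <- rep_len(genotype, n)
  phenotype <- rep_len(phenotype, n)
  f <- model$penetrance[genotype]
  out <- ifelse(phenotype == "affected", f,
         ifelse(phenotype == "unaffected", 1 - f, 1))
  unname(out)
}

#' Hardy-Weinberg founder genotype prior
#'
#' Founders are drawn from a population in Hardy-Weinberg equilibrium at the
#' disease locus: P(DD) = q^2, P(Dd) = 2q(1-q), P(dd) = (1-q)^2.
#'
#' @param model a [disease_model()].
#' @param genotype optional `"DD"`/`"Dd"`/`"dd"`; if omitted, the full named
#'   prior vector is returned.
#' @return probability or named probability vector summing to 1.
#' @export
founder_genotype_prior <- function(model, genotype = NULL) {
  stopifnot(inherits(model, "disease_model"))
  q <- model$disease_allele_freq
  prior <- c(DD = q^2, Dd = 2 * q * (1 - q), dd = (1 - q)^2)
  if (is.null(genotype)) return(prior)
  stopifnot(all(genotype %in% names(prior)))
  unname(prior[genotype])
}

#' Read disease-model parameters from a key-value config file
#'
#' Accepts a YAML (or plain `key: value`) file with keys
#' `disease_allele_freq` and `penetrance` (list/vector of three values).
#' Missing keys fall back to the [disease_model()] defaults.
#'
#' @param path file path.
#' @return a [disease_model()].
#' @export
read_model_config <- function(path) {
  if (!file.exists(path))
    stop_lx("lx_missing_file", "model config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  disease_model(
    disease_allele_freq = cfg$disease_allele_freq %||% 1e-4,
    penetrance = unlist(cfg$penetrance) %||% c(0.9, 0.9, 0)
  )
}
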