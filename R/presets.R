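#' Genotype presets for the repertoire simulator
#'
#' A preset bundles the parameters of one simulated genotype. Two modes
#' exist. In *empirical* mode the light-chain repertoire is drawn from
#' frequency tables (kappa/lambda share, lambda-family weights, Igk-J
#' weights, per-locus unproductive fractions), which lets the analysis
#' pipeline be validated by parameter recovery. In *mechanistic* mode the
#' light chain is produced by a sequential rearrangement state machine that
#' embodies the three determinants of lambda light-chain generation: the
#' probability and kinetics of Igl locus opening, the life-span of the
#' developing cell, and the efficiency of receptor editing.
#'
#' Built-in empirical presets:
#' \describe{
#'   \item{ctrl}{wild-type-like control: kappa share 0.83 among cells with a
#'     productive light chain; lambda-family weights (lambda1, lambda2,
#'     lambda3) = (0.44, 0.41, 0.15); Igkj5 share 0.10; unproductive read
#'     fractions IGH 0.92, IGK 0.10, IGL 0.10.}
#'   \item{bko}{B-cell Kidins220-knockout-like skew: kappa share 0.98;
#'     lambda-family weights (0.69, 0.12, 0.19) (second-cassette genes
#'     favoured); Igkj5 share 0.142 (increased receptor editing signature);
#'     unproductive fractions IGH 0.93, IGK 0.12, IGL 0.20.}
#'   \item{wildtype_lambda}{lambda-only repertoire with the canonical mature
#'     wild-type family distribution (0.62, 0.31, 0.07).}
#' }
#' Built-in mechanistic presets: `kappa_ko` (silenced Igk locus; every
#' surviving cell is lambda) and `macroself` (every kappa rearrangement is
#' autoreactive, forcing editing until lambda or death).
#'
#' The `kappa_fraction` of an empirical preset is defined as the kappa share
#' among cells with a *productive* light chain (what a sorted-BCR+ isotype
#' measurement reports); the simulator back-solves the raw locus probability
#' from the per-locus unproductive fractions.
#'
#' @param name one of `"ctrl"`, `"bko"`, `"wildtype_lambda"`, `"kappa_ko"`,
#'   `"macroself"`, or `"custom"` (starts from `ctrl` values).
#' @param ... named overrides of any preset field.
#' @return An object of class `genotype_preset` (a named list).
#' @examples
#' p <- genotype_preset("ctrl")
#' p$kappa_fraction
#' genotype_preset("custom", kappa_fraction = 0.5)$kappa_fraction
#' @export
genotype_preset <- function(name = c("ctrl", "bko", "wildtype_lambda",
                                     "kappa_ko", "macroself", "custom"),
                            ...) {
  name <- match.arg(name)
  base <- list(
    name = name,
    mode = "empirical",
    kappa_fraction = 0.83,
    lambda_family_weights = c(lambda1 = 0.44, lambda2 = 0.41, lambda3 = 0.15),
    igl_v2_share_within_lambda2 = 0.4,   # Iglv2 vs Iglv3 split inside lambda2
    igk_j_weights = c(Igkj1 = 0.30, Igkj2 = 0.30, Igkj4 = 0.30, Igkj5 = 0.10),
    unproductive_fraction_per_locus = c(IGH = 0.92, IGK = 0.10, IGL = 0.10),
    stop_codon_share_of_unproductive = 0.5,
    # junctional diversity
    trim_p = 0.25, trim_cap = 6L,
    n_add_heavy = 4, n_add_light = 1,
    # mechanistic state machine
    p_igk_productive = 0.5,
    p_igl_productive = 0.5,
    p_autoreactive_kappa = 0.25,
    max_edit_attempts = 4L,
    p_igl_open = 0.8,
    survival_halflife = 6,
    kappa_silenced = FALSE,
    kappa_forced_autoreactive = FALSE,
    clonal_expansion = NULL
  )
  preset <- switch(name,
    ctrl = base,
    bko = modifyList(base, list(
      kappa_fraction = 0.98,
      lambda_family_weights = c(lambda1 = 0.69, lambda2 = 0.12, lambda3 = 0.19),
      igk_j_weights = c(Igkj1 = 0.286, Igkj2 = 0.286, Igkj4 = 0.286,
                        Igkj5 = 0.142),
      unproductive_fraction_per_locus = c(IGH = 0.93, IGK = 0.12, IGL = 0.20)
    )),
    wildtype_lambda = modifyList(base, list(
      kappa_fraction = 0,
      lambda_family_weights = c(lambda1 = 0.62, lambda2 = 0.31, lambda3 = 0.07)
    )),
    kappa_ko = modifyList(base, list(
      mode = "mechanistic", kappa_silenced = TRUE, kappa_fraction = 0,
      p_igl_open = 1
    )),
    macroself = modifyList(base, list(
      mode = "mechanistic", kappa_forced_autoreactive = TRUE
    )),
    custom = base
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(preset))
    if (length(bad)) stop("unknown preset fields: ", paste(bad, collapse = ", "))
    preset <- modifyList(preset, overrides)
  }
  validate_preset(preset)
  preset
}

#' Validate a genotype preset
#'
#' Checks probability ranges, simplex normalisation of the weight tables
#' (within 1e-9), the consistency between lambda-family weights and the
#' cassette topology, and flags the contradiction of a nonzero kappa
#' fraction on a silenced Igk locus.
#'
#' @param preset a `genotype_preset` or plain list with the same fields.
#' @return The preset, classed, invisibly returned on success.
#' @export
validate_preset <- function(preset) {
  p <- preset
  probs <- c(p$kappa_fraction, p$p_igk_productive, p$p_igl_productive,
             p$p_autoreactive_kappa, p$p_igl_open, p$trim_p,
             p$stop_codon_share_of_unproductive,
             p$igl_v2_share_within_lambda2,
             p$unproductive_fraction_per_locus)
  if (any(probs < 0 | probs > 1)) stop("preset probabilities must lie in [0, 1]")
  if (!.is_simplex(p$lambda_family_weights))
    stop("lambda_family_weights must sum to 1")
  if (!.is_simplex(p$igk_j_weights)) stop("igk_j_weights must sum to 1")
  if (!setequal(names(p$lambda_family_weights),
                c("lambda1", "lambda2", "lambda3")))
    stop("lambda_family_weights must cover lambda1..lambda3")
  if ("Igkj3" %in% names(p$igk_j_weights))
    stop("igk_j_weights must not include the pseudogene Igkj3")
  if (isTRUE(p$kappa_silenced) && p$mode == "empirical" && p$kappa_fraction > 0)
    stop("preset contradiction: kappa_fraction > 0 with kappa_silenced = TRUE")
  if (!is.null(p$clonal_expansion)) {
    ce <- p$clonal_expansion
    if (ce$n_clones < 1 || ce$clone_mass <= 0 ||
        ce$n_clones * ce$clone_mass > 1)
      stop("clonal_expansion: need n_clones >= 1 and n_clones * clone_mass <= 1")
  }
  invisible(structure(p, class = "genotype_preset"))
}

# lambda-family weights expressed as per-gene V and J weights under the
# cassette map (lambda1 -> Iglv1 x Iglj1, lambda3 -> Iglv1 x Iglj3,
# lambda2 -> {Iglv2, Iglv3} x Iglj2)
.igl_gene_weights <- function(preset) {
  w <- preset$lambda_family_weights
  s2 <- preset$igl_v2_share_within_lambda2
  list(
    v = c(Iglv1 = unname(w["lambda1"] + w["lambda3"]),
          Iglv2 = unname(w["lambda2"] * s2),
          Iglv3 = unname(w["lambda2"] * (1 - s2))),
    j = c(Iglj1 = unname(w["lambda1"]), Iglj2 = unname(w["lambda2"]),
          Iglj3 = unname(w["lambda3"]))
  )
}
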