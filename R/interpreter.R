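variant_classes <- c("pathogenic", "likely_pathogenic", "VUS",
                     "likely_benign", "benign")
plp <- c("pathogenic", "likely_pathogenic")

#' Assemble a per-case molecular profile
#'
#' Bundles the upstream module outputs for one case: classified germline
#' and somatic variant calls, per-gene LOH calls, panel MSI status, MLH1
#' promoter methylation and (optionally) the IHC protein-loss pattern.
#' Classification labels are external inputs (clinical variant
#' classification is out of scope for the callers).
#'
#' @param germline_variants,somatic_variants Data frames with at least
#'   `gene` and `classification` (one of pathogenic, likely_pathogenic,
#'   VUS, likely_benign, benign); an optional `variant` column labels the
#'   change for evidence strings.
#' @param gene_loh Data frame with `gene` (Lynch genes only) and logical
#'   `loh`.
#' @param msi_status `"High"`, `"Stable"`, `"Failed"` or `NA`.
#' @param mlh1_methylated Logical flag or `NA` (not assayed).
#' @param ihc_absent Optional character vector of proteins with absent
#'   staining, subset of MLH1, MSH2, MSH6, PMS2.
#' @return A list of class `case_profile`.
#' @export
case_profile <- function(germline_variants = NULL, somatic_variants = NULL,
                         gene_loh = NULL, msi_status = NA_character_,
                         mlh1_methylated = NA, ihc_absent = NULL) {
  empty_var <- tibble(gene = character(0), variant = character(0),
                      classification = character(0))
  fix_var <- function(v, what) {
    if (is.null(v) || nrow(as_tibble(v)) == 0) return(empty_var)
    v <- as_tibble(v)
    if (!all(c("gene", "classification") %in% names(v))) {
      abort(sprintf("`%s` needs columns gene and classification", what))
    }
    bad <- setdiff(v$classification, variant_classes)
    if (length(bad) > 0) {
      abort(sprintf("unknown classification label(s) in `%s`: %s", what,
                    paste(bad, collapse = ", ")))
    }
    if (!"variant" %in% names(v)) v$variant <- NA_character_
    select(v, "gene", "variant", "classification")
  }
  g <- fix_var(germline_variants, "germline_variants")
  s <- fix_var(somatic_variants, "somatic_variants")
  loh <- if (is.null(gene_loh)) {
    tibble(gene = character(0), loh = logical(0))
  } else {
    as_tibble(gene_loh)
  }
  if (nrow(loh) > 0) {
    if (!all(c("gene", "loh") %in% names(loh))) {
      abort("`gene_loh` needs columns gene and loh")
    }
    bad <- setdiff(loh$gene, lynch_genes())
    if (length(bad) > 0) {
      abort(sprintf("LOH call for non-Lynch gene(s): %s", paste(bad, collapse = ", ")))
    }
  }
  if (!is.na(msi_status) && !msi_status %in% c("High", "Stable", "Failed")) {
    abort("`msi_status` must be High, Stable, Failed or NA")
  }
  if (!is.null(ihc_absent)) {
    bad <- setdiff(ihc_absent, c("MLH1", "MSH2", "MSH6", "PMS2"))
    if (length(bad) > 0) {
      abort(sprintf("unknown IHC protein(s): %s", paste(bad, collapse = ", ")))
    }
  }
  structure(list(germline_variants = g, somatic_variants = s,
                 gene_loh = select(loh, "gene", "loh"),
                 msi_status = msi_status,
                 mlh1_methylated = mlh1_methylated,
                 ihc_absent = ihc_absent),
            class = "case_profile")
}

classify_gene_scenario <- function(profile, gene) {
  g <- filter(profile$germline_variants, .data$gene == !!gene)
  s <- filter(profile$somatic_variants, .data$gene == !!gene)
  loh <- any(profile$gene_loh$loh[profile$gene_loh$gene == gene])
  meth <- gene == "MLH1" && isTRUE(profile$mlh1_methylated)
  germ_plp <- any(g$classification %in% plp)
  germ_vus <- any(g$classification == "VUS")
  n_som <- sum(s$classification %in% plp)

  if (germ_plp) {
    if (loh) "B" else if (n_som >= 2) "H" else if (n_som == 1) "A" else "none"
  } else if (germ_vus && n_som >= 1) {
    "E"
  } else if (n_som >= 2 && loh) {
    "F"
  } else if (n_som >= 1 && loh) {
    "C"
  } else if (n_som >= 2) {
    "D"
  } else if (meth && loh && nrow(g) == 0 && nrow(s) == 0) {
    "G"
  } else {
    "none"
  }
}

scenario_rank <- c(A = 1, B = 2, H = 3, E = 4, C = 5, D = 6, F = 7, G = 8,
                   none = 99)
scenario_diagnosis <- c(A = "lynch_confirmed", B = "lynch_confirmed",
                        H = "lynch_confirmed", E = "vus_upgrade_candidate",
                        C = "lynch_ruled_out_double_somatic",
                        D = "lynch_ruled_out_double_somatic",
                        F = "lynch_ruled_out_double_somatic",
                        G = "sporadic_methylation", none = "inconclusive")

#' Classify a case into a two-hit molecular scenario
#'
#' Evaluates each gene with molecular findings independently against the
#' two-hit scenario archetypes -- (A) germline pathogenic + one somatic
#' hit, (B) germline pathogenic + LOH (with or without an extra somatic
#' hit), (H) germline pathogenic + two or more somatic hits, (E) germline
#' VUS + somatic pathogenic hit, (F) multiple somatic hits + LOH, (C) one
#' somatic hit + LOH, (D) two or more somatic hits, (G) MLH1 promoter
#' methylation + LOH with no mutations -- and reports the
#' highest-precedence gene as the case-level scenario. Germline-bearing
#' scenarios outrank somatic-only ones because they dominate clinical
#' meaning; methylation ranks last. Phase cannot be assessed from panel
#' data: co-occurring hits in one gene are interpreted as biallelic.
#'
#' @param profile A [case_profile()].
#' @return A list of class `scenario_call`: `scenario`, `affected_gene`,
#'   `diagnosis`, `evidence` (character vector), `per_gene` (tibble),
#'   `ihc_concordant`.
#' @export
classify_scenario <- function(profile) {
  stopifnot(inherits(profile, "case_profile"))
  genes <- sort(unique(c(profile$germline_variants$gene,
                         profile$somatic_variants$gene,
                         profile$gene_loh$gene[profile$gene_loh$loh],
                         if (isTRUE(profile$mlh1_methylated)) "MLH1")))
  per_gene <- purrr::map_dfr(genes, function(g) {
    tibble(gene = g, scenario = classify_gene_scenario(profile, g))
  })
  if (nrow(per_gene) == 0) {
    per_gene <- tibble(gene = character(0), scenario = character(0))
  }
  hit <- per_gene[per_gene$scenario != "none", , drop = FALSE]
  if (nrow(hit) == 0) {
    scenario <- "none"
    affected <- NA_character_
  } else {
    best <- hit[order(scenario_rank[hit$scenario], hit$gene), ]
    scenario <- best$scenario[1]
    affected <- best$gene[1]
  }

  evidence <- character(0)
  v_lab <- function(v) ifelse(is.na(v$variant), "variant", v$variant)
  gv <- profile$germline_variants
  if (nrow(gv) > 0) {
    evidence <- c(evidence, sprintf("germline %s %s (%s)", gv$gene,
                                    v_lab(gv), gv$classification))
  }
  sv <- profile$somatic_variants
  if (nrow(sv) > 0) {
    evidence <- c(evidence, sprintf("somatic %s %s (%s)", sv$gene,
                                    v_lab(sv), sv$classification))
  }
  lg <- profile$gene_loh$gene[profile$gene_loh$loh]
  if (length(lg) > 0) evidence <- c(evidence, sprintf("LOH in %s", lg))
  if (isTRUE(profile$mlh1_methylated)) {
    evidence <- c(evidence, "MLH1 promoter hypermethylation")
  }
  if (!is.na(profile$msi_status)) {
    evidence <- c(evidence, sprintf("MSI status: %s", profile$msi_status))
  }
  if (scenario == "none" && any(gv$classification %in% plp)) {
    evidence <- c(evidence,
                  "germline pathogenic variant without a detected second hit")
  }

  call <- structure(list(scenario = scenario, affected_gene = affected,
                         diagnosis = unname(scenario_diagnosis[scenario]),
                         evidence = evidence, per_gene = per_gene,
                         ihc_concordant = NA),
                    class = "scenario_call")
  if (!is.null(profile$ihc_absent)) {
    chk <- check_ihc_concordance(profile, call)
    call$ihc_concordant <- chk$concordant
    if (!is.na(chk$note)) call$evidence <- c(call$evidence, chk$note)
  }
  call
}

#' @export
print.scenario_call <- function(x, ...) {
  cat(sprintf("<scenario_call> scenario %s (%s)%s\n", x$scenario, x$diagnosis,
              if (is.na(x$affected_gene)) ""
              else sprintf(", affected gene %s", x$affected_gene)))
  for (e in x$evidence) cat("  -", e, "\n")
  invisible(x)
}

#' @export
tidy.scenario_call <- function(x, ...) x$per_gene

#' @export
glance.scenario_call <- function(x, ...) {
  tibble(scenario = x$scenario, affected_gene = x$affected_gene,
         diagnosis = x$diagnosis, n_evidence = length(x$evidence),
         ihc_concordant = x$ihc_concordant)
}

#' Expected IHC protein-loss pattern for a defective Lynch gene
#'
#' MLH1 and PMS2 heterodimerize, as do MSH2 and MSH6: loss of the obligate
#' partner (MLH1, MSH2) destabilizes both proteins, while loss of the
#' junior partner (PMS2, MSH6) leaves the other detectable. EPCAM
#' 3'-deletions silence MSH2 and phenocopy its pattern.
#'
#' @param gene One of the five Lynch genes.
#' @return Character vector of proteins expected absent on IHC.
#' @export
#' @examples
#' expected_ihc_pattern("MLH1")
expected_ihc_pattern <- function(gene) {
  patterns <- list(MLH1 = c("MLH1", "PMS2"), MSH2 = c("MSH2", "MSH6"),
                   MSH6 = "MSH6", PMS2 = "PMS2", EPCAM = c("MSH2", "MSH6"))
  if (!gene %in% names(patterns)) {
    abort(sprintf("'%s' is not a Lynch gene", gene))
  }
  patterns[[gene]]
}

#' Check IHC concordance with the molecular scenario
#'
#' Concordant when the observed absent-protein set equals the pattern
#' expected for the affected gene. Mismatches produce a note, never an
#' error; with no IHC or no affected gene the flag is `NA`.
#'
#' @param profile A [case_profile()] with `ihc_absent` set.
#' @param call A [classify_scenario()] result.
#' @return List with `concordant` (logical or NA) and `note`.
#' @export
check_ihc_concordance <- function(profile, call) {
  if (is.null(profile$ihc_absent)) {
    return(list(concordant = NA, note = NA_character_))
  }
  if (is.na(call$affected_gene)) {
    return(list(concordant = NA,
                note = "IHC provided but no affected gene identified"))
  }
  expected <- expected_ihc_pattern(call$affected_gene)
  ok <- setequal(expected, profile$ihc_absent)
  note <- if (ok) {
    sprintf("IHC concordant: absent {%s} matches a %s defect",
            paste(sort(profile$ihc_absent), collapse = ", "),
            call$affected_gene)
  } else {
    sprintf("IHC discordant: absent {%s}, but a %s defect predicts {%s}",
            paste(sort(profile$ihc_absent), collapse = ", "),
            call$affected_gene, paste(sort(expected), collapse = ", "))
  }
  list(concordant = ok, note = note)
}
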