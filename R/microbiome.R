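#' Identify pdu-positive genomes
#'
#' A genome is pdu-positive when it carries at least one (mode "any") or all
#' (mode "all") of the required diol/glycerol dehydratase subunit genes,
#' by default the three pduCDE subunits.
#'
#' @param pdu_genes Data frame with a `genome_id` column and one
#'   logical/0-1 column per pdu gene. Row ids must be unique.
#' @param required_genes Gene columns defining positivity.
#' @param mode "any" (default) or "all".
#' @return List with `positive_ids`, `n_positive`, `n_genomes` and
#'   `percent_positive` (full precision).
#' @export
pdu_positive <- function(pdu_genes,
                         required_genes = c("pduC", "pduD", "pduE"),
                         mode = c("any", "all")) {
  mode <- match.arg(mode)
  require_columns(pdu_genes, c("genome_id", required_genes),
                  "pdu gene matrix")
  if (anyDuplicated(pdu_genes$genome_id)) {
    stop("duplicate genome_id in pdu gene matrix", call. = FALSE)
  }
  m <- sapply(pdu_genes[required_genes], function(x) as.logical(x))
  m <- matrix(m, nrow = nrow(pdu_genes))
  hits <- if (mode == "any") rowSums(m) >= 1 else rowSums(m) == ncol(m)
  list(positive_ids = pdu_genes$genome_id[hits],
       n_positive = sum(hits),
       n_genomes = nrow(pdu_genes),
       percent_positive = 100 * sum(hits) / nrow(pdu_genes))
}

#' Per-donor counts of detected pdu-positive species
#'
#' Counts, for each donor, how many pdu-positive taxa were detected above
#' the limit of detection in at least one of the donor's samples.
#'
#' @param positive_ids Taxon ids considered pdu-positive.
#' @param detection Data frame with columns `donor`, `taxon` and either a
#'   logical `detected` or numeric `copies_per_g` + `lod` (detected when
#'   copies > lod).
#' @return List with `per_donor` (tibble donor x n_species),
#'   `cohort_median` and `cohort_min`.
#' @export
per_donor_pdu_species <- function(positive_ids, detection) {
  require_columns(detection, c("donor", "taxon"), "detection table")
  if (nrow(detection) == 0) stop("empty detection table", call. = FALSE)
  if (!"detected" %in% names(detection)) {
    require_columns(detection, c("copies_per_g", "lod"), "detection table")
    detection$detected <- detection$copies_per_g > detection$lod
  }
  per_donor <- detection |>
    dplyr::filter(.data$taxon %in% positive_ids, .data$detected) |>
    dplyr::distinct(.data$donor, .data$taxon) |>
    dplyr::count(.data$donor, name = "n_species") |>
    tidyr::complete(donor = unique(detection$donor),
                    fill = list(n_species = 0L))
  list(per_donor = per_donor,
       cohort_median = stats::median(per_donor$n_species),
       cohort_min = min(per_donor$n_species))
}

#' Per-taxon share of an absolute abundance signal
#'
#' Fraction of the summed per-sample signal (e.g. pduC copies per gram)
#' contributed by each taxon. Values at or below the limit of detection are
#' substituted with LOD/2 ("half", default) or dropped ("drop") before the
#' shares are formed; when every taxon in a sample is below LOD the shares
#' are undefined (NA) and flagged.
#'
#' @param abundances Data frame with columns `sample`, `taxon`,
#'   `copies_per_g` and `lod`.
#' @param lod_substitute "half" or "drop".
#' @return Tibble: `sample`, `taxon`, `copies_used`, `share` (fraction of
#'   the per-sample sum), `below_lod`, `all_below_lod`.
#' @export
taxon_share <- function(abundances, lod_substitute = c("half", "drop")) {
  lod_substitute <- match.arg(lod_substitute)
  require_columns(abundances, c("sample", "taxon", "copies_per_g", "lod"),
                  "abundance table")
  x <- abundances |>
    dplyr::mutate(below_lod = .data$copies_per_g <= .data$lod,
                  copies_used = dplyr::case_when(
                    !.data$below_lod ~ .data$copies_per_g,
                    lod_substitute == "half" ~ .data$lod / 2,
                    TRUE ~ 0)) |>
    dplyr::group_by(.data$sample) |>
    dplyr::mutate(all_below_lod = all(.data$below_lod),
                  share = dplyr::if_else(.data$all_below_lod, NA_real_,
                                         .data$copies_used /
                                           sum(.data$copies_used))) |>
    dplyr::ungroup()
  if (any(x$all_below_lod)) {
    message("sample(s) with all taxa below LOD flagged: ",
            paste(unique(x$sample[x$all_below_lod]), collapse = ", "))
  }
  x |> dplyr::select("sample", "taxon", "copies_used", "share",
                     "below_lod", "all_below_lod")
}

#' Occurrence and median abundance per taxon
#'
#' Occurrence is the percentage of samples in which a taxon exceeds the
#' threshold; the median abundance is taken over all samples including
#' zeros.
#'
#' @param abundances Data frame with columns `sample`, `taxon` and `value`
#'   (relative abundance or absolute copies).
#' @param threshold Detection threshold (value must be strictly greater).
#' @return Tibble: `taxon`, `n_samples`, `occurrence_pct`, `median_value`.
#' @export
prevalence <- function(abundances, threshold = 0) {
  require_columns(abundances, c("sample", "taxon", "value"),
                  "abundance table")
  if (nrow(abundances) == 0) stop("empty abundance table", call. = FALSE)
  stopifnot(threshold >= 0)
  abundances |>
    dplyr::group_by(.data$taxon) |>
    dplyr::summarise(n_samples = dplyr::n(),
                     occurrence_pct = 100 * mean(.data$value > threshold),
                     median_value = stats::median(.data$value),
                     .groups = "drop")
}

#' Short-chain fatty acid proportions and butyrate:propionate ratio
#'
#' Expresses acetate, propionate and butyrate as percentages of their sum
#' and computes the butyrate:propionate ratio. Proportions are undefined
#' for an all-zero profile and the ratio is undefined when propionate is
#' zero; both are returned as NA and flagged.
#'
#' @param scfa Data frame with columns `sample`, `acetate`, `propionate`,
#'   `butyrate` (any consistent concentration unit).
#' @return Tibble: `sample`, `acetate_pct`, `propionate_pct`,
#'   `butyrate_pct`, `but_prop_ratio`, `total`, `undefined`.
#' @export
scfa_proportions <- function(scfa) {
  require_columns(scfa, c("sample", "acetate", "propionate", "butyrate"),
                  "SCFA table")
  if (any(scfa$acetate < 0 | scfa$propionate < 0 | scfa$butyrate < 0)) {
    stop("SCFA values must be non-negative", call. = FALSE)
  }
  total <- scfa$acetate + scfa$propionate + scfa$butyrate
  undefined <- total <= 0
  if (any(undefined)) {
    message("all-zero SCFA profile(s) flagged: ",
            paste(scfa$sample[undefined], collapse = ", "))
  }
  tibble::tibble(
    sample = scfa$sample,
    acetate_pct = ifelse(undefined, NA_real_, 100 * scfa$acetate / total),
    propionate_pct = ifelse(undefined, NA_real_,
                            100 * scfa$propionate / total),
    butyrate_pct = ifelse(undefined, NA_real_, 100 * scfa$butyrate / total),
    but_prop_ratio = ifelse(scfa$propionate > 0,
                            scfa$butyrate / scfa$propionate, NA_real_),
    total = total,
    undefined = undefined)
}

#' Report absolute abundances on the log10 scale
#'
#' Log10 of copies per gram for detected values; below-LOD values are
#' reported as NA with a `below_lod` flag rather than log of zero.
#'
#' @param copies_per_g Numeric vector of absolute abundances.
#' @param lod Limit of detection (scalar or vector).
#' @return Tibble: `log10_copies`, `below_lod`.
#' @export
log10_abundance <- function(copies_per_g, lod) {
  below <- copies_per_g <= lod
  tibble::tibble(log10_copies = ifelse(below, NA_real_, log10(copies_per_g)),
                 below_lod = below)
}
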