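#' Default antibody panel and cell-type surface signatures
#'
#' The panel mimics a 40-plex PBMC surface staining panel: the markers used by
#' the major-type gating scheme (CD3, CD4, CD8, CD14, CD16, CD19, CD20, CD56,
#' CD123, CD206), the markers used for subcluster splitting (CD11c, CD25,
#' CD127, CXCR3, CCR2, CD163, CD152, CD36), a chemokine receptor with known
#' inherent background (CD197, excluded from analysis by default), and
#' lineage/activation markers that round the panel out to 40-plex; every
#' marker has a positive population in at least one type, as a designed
#' panel would.
#'
#' @return character vector of 40 marker names.
#' @export
default_markers <- function() {
  c("CD3", "CD4", "CD8", "CD14", "CD16", "CD19", "CD20", "CD56", "CD123",
    "CD206", "CD11c", "CD25", "CD127", "CXCR3", "CCR2", "CD163", "CD152",
    "CD36", "CD197",
    "CD27", "CD28", "CD38", "CD57", "CD45RA", "CD69", "CD95", "CD86",
    "CD40", "CXCR5", "CCR4", "CCR6", "CD161", "CD24", "CD1c", "KLRG1",
    "TIGIT", "CD39", "HLA-DR", "IgD", "PD-1")
}

#' @rdname default_markers
#' @return for `default_signatures()`, a logical matrix (7 major types x 40
#'   markers); `TRUE` marks a surface protein genuinely expressed by that
#'   type.
#' @export
default_signatures <- function() {
  markers <- default_markers()
  types <- c("B", "CD4T", "CD8T", "CM", "INT", "NCM", "NK")
  sig <- matrix(FALSE, length(types), length(markers),
                dimnames = list(types, markers))
  pos <- list(
    B    = c("CD19", "CD20", "CD24", "HLA-DR", "IgD", "CD40", "CXCR5",
             "CD1c", "CD38"),
    CD4T = c("CD3", "CD4", "CD127", "CD27", "CD28", "CD95", "CCR4",
             "CCR6", "TIGIT", "CD39", "PD-1", "CD45RA", "CD197"),
    CD8T = c("CD3", "CD8", "CD27", "CD28", "CD57", "CD95", "CD161",
             "KLRG1", "CD69"),
    CM   = c("CD14", "CD11c", "CCR2", "CD36", "HLA-DR", "CD86", "CD40"),
    INT  = c("CD14", "CD16", "CD11c", "HLA-DR", "CD86", "CD123", "CD206"),
    NCM  = c("CD16", "CD11c", "CD36", "HLA-DR"),
    NK   = c("CD56", "CD57", "KLRG1", "CD38", "CD69"))
  for (t in types) sig[t, pos[[t]]] <- TRUE
  sig
}

#' @rdname default_markers
#' @return for `default_sub_signatures()`, a named list: type -> named
#'   vector of per-marker positivity fractions. These markers are positive
#'   in only a random subset of the type's cells, giving each major type
#'   genuine subcluster structure (memory/activation subsets, CD163/CD152
#'   monocyte states, CD16-bright NK cells, ...).
#' @export
default_sub_signatures <- function() {
  list(
    B    = c(CD25 = 0.30, CXCR3 = 0.30),
    CD4T = c(CXCR3 = 0.35, CD25 = 0.20, CCR2 = 0.15, CD11c = 0.05,
             CD56 = 0.03),
    CD8T = c(CXCR3 = 0.40, CD11c = 0.10, CD16 = 0.05),
    CM   = c(CD163 = 0.50, CD152 = 0.10),
    INT  = c(CD152 = 0.50, CD163 = 0.30),
    NCM  = c(CD152 = 0.40),
    NK   = c(CD11c = 0.30, CD16 = 0.60))
}

default_groups <- function()
  c("HIVneg", "HIVposCVDneg", "HIVposCVDpos", "HIVposCVDposCRT")

# Baseline PBMC composition; realistic relative abundances for the 7 types.
default_type_fractions <- function()
  c(B = 0.10, CD4T = 0.30, CD8T = 0.15, CM = 0.27,
    INT = 0.03, NCM = 0.05, NK = 0.10)

default_rna_rates <- function(signatures) {
  markers <- colnames(signatures)
  sig_genes <- markers[1:19]                       # genes matched to ADTs
  genes <- c(sig_genes, sprintf("G%03d", 20:485))
  rates <- matrix(rep(c(0.1, 0.3, 0.6, 1, 2), length.out = length(genes)),
                  nrow(signatures), length(genes), byrow = TRUE,
                  dimnames = list(rownames(signatures), genes))
  # transcripts of expressed surface proteins are high in the matching type
  for (g in sig_genes)
    rates[, g] <- ifelse(signatures[, g], 3, 0.05)
  rates
}

#' Build a synthetic-cohort configuration
#'
#' The defaults encode the emulated study design: 4 participant groups
#' (HIV-negative, HIV-positive without CVD, HIV-positive with CVD untreated /
#' CRT-treated) of 8 matched participants each, ~1,300 cells per participant,
#' 4 sample tags per loading plate, a 7.5\% doublet formation rate, 40
#' antibodies and a 485-gene targeted panel. ADT counts are
#' round-lognormal (background vs signal component per marker), transcripts
#' are Poisson with per-(type, gene) rates, sample tags are Poisson with one
#' dominant tag per singlet. Planted effects (differential expression and
#' proportion shifts) give the downstream statistics a known truth to
#' recover.
#'
#' @param n_per_group participants per group.
#' @param groups character vector of group labels.
#' @param cells_per_participant singlet cells per participant.
#' @param type_fractions named baseline cell-type probabilities (sum to 1).
#' @param signatures logical type x marker matrix of truly expressed markers.
#' @param sub_signatures named list (type -> named fraction vector): markers
#'   positive in only that fraction of the type's cells, creating known
#'   subcluster structure; overrides `signatures` for those (type, marker)
#'   pairs.
#' @param rna_rates numeric type x gene matrix of expected counts.
#' @param adt_signal,adt_background lists with `meanlog`, `sdlog` (scalars or
#'   per-marker named vectors) for the positive and background lognormal
#'   components.
#' @param planted_de data.frame with columns `gene`, `type`, `group`, `lfc`:
#'   the gene's Poisson rate is multiplied by `2^lfc` for cells of that type
#'   in that group.
#' @param planted_prop_shift data.frame with columns `type`, `group`,
#'   `multiplier`: that type's baseline fraction is multiplied and the
#'   group's fractions renormalized.
#' @param doublet_rate doublet formation rate in `[0, 0.5)`.
#' @param n_tags_per_plate sample tags (and thus participants) per plate.
#' @param tag_ambient_lambda,tag_dominant_lambda Poisson means for ambient
#'   and dominant sample-tag counts.
#' @param seed master seed; all stage substreams derive from it.
#' @return a `synthetic_config` object.
#' @export
synthetic_config <- function(n_per_group = 8,
                             groups = default_groups(),
                             cells_per_participant = 1300,
                             type_fractions = default_type_fractions(),
                             signatures = default_signatures(),
                             sub_signatures = default_sub_signatures(),
                             rna_rates = default_rna_rates(signatures),
                             adt_signal = list(meanlog = log(80), sdlog = 0.45),
                             adt_background = list(meanlog = log(2), sdlog = 0.45),
                             planted_de = data.frame(
                               gene  = c("G021", "G022", "G023"),
                               type  = c("CD4T", "CM", "CD8T"),
                               group = c("HIVposCVDpos", "HIVposCVDpos",
                                         "HIVposCVDposCRT"),
                               lfc   = c(2, 1.5, -2)),
                             planted_prop_shift = data.frame(
                               type = "INT", group = "HIVposCVDpos",
                               multiplier = 2),
                             doublet_rate = 0.075,
                             n_tags_per_plate = 4,
                             tag_ambient_lambda = 1,
                             tag_dominant_lambda = 60,
                             seed = 42) {
  fail <- function(field, why) stop(sprintf("invalid config: %s %s", field, why),
                                    call. = FALSE)
  if (n_per_group < 1) fail("n_per_group", "must be >= 1")
  if (cells_per_participant < 1) fail("cells_per_participant", "must be >= 1")
  if (doublet_rate < 0 || doublet_rate >= 0.5)
    fail("doublet_rate", "must lie in [0, 0.5)")
  if (abs(sum(type_fractions) - 1) > 1e-8)
    fail("type_fractions", "must sum to 1")
  if (any(type_fractions < 0)) fail("type_fractions", "must be non-negative")
  if (!all(rownames(signatures) %in% names(type_fractions)))
    fail("signatures", "row names must match type_fractions names")
  if (!identical(rownames(rna_rates), rownames(signatures)))
    fail("rna_rates", "row names must match signature types")
  if (any(rna_rates <= 0)) fail("rna_rates", "must be > 0")
  if (any(unlist(adt_signal["sdlog"]) <= 0)) fail("adt_signal$sdlog", "must be > 0")
  if (any(unlist(adt_background["sdlog"]) <= 0))
    fail("adt_background$sdlog", "must be > 0")
  if (n_tags_per_plate < 2) fail("n_tags_per_plate", "must be >= 2")
  if (nrow(planted_de) &&
      (!all(planted_de$gene %in% colnames(rna_rates)) ||
       !all(planted_de$type %in% rownames(rna_rates)) ||
       !all(planted_de$group %in% groups)))
    fail("planted_de", "references unknown gene, type or group")
  if (nrow(planted_prop_shift) &&
      (!all(planted_prop_shift$type %in% names(type_fractions)) ||
       !all(planted_prop_shift$group %in% groups)))
    fail("planted_prop_shift", "references unknown type or group")
  if (length(sub_signatures)) {
    if (!all(names(sub_signatures) %in% rownames(signatures)))
      fail("sub_signatures", "names must be signature types")
    fr <- unlist(sub_signatures)
    if (any(fr <= 0) || any(fr >= 1))
      fail("sub_signatures", "fractions must lie in (0, 1)")
    if (!all(unlist(lapply(sub_signatures, names)) %in% colnames(signatures)))
      fail("sub_signatures", "references unknown markers")
  }

  # per-group type fractions: baseline with planted shifts, renormalized
  frac <- matrix(rep(type_fractions, each = length(groups)),
                 length(groups), length(type_fractions),
                 dimnames = list(groups, names(type_fractions)))
  if (nrow(planted_prop_shift))
    for (i in seq_len(nrow(planted_prop_shift)))
      frac[planted_prop_shift$group[i], planted_prop_shift$type[i]] <-
        frac[planted_prop_shift$group[i], planted_prop_shift$type[i]] *
        planted_prop_shift$multiplier[i]
  frac <- frac / rowSums(frac)

  expand <- function(x, nm) {
    out <- rep(x, length.out = length(nm))
    if (!is.null(names(x))) out <- x[nm]
    setNames(as.numeric(out), nm)
  }
  markers <- colnames(signatures)
  structure(list(
    n_per_group = as.integer(n_per_group), groups = groups,
    cells_per_participant = as.integer(cells_per_participant),
    cell_type_fractions = frac, signatures = signatures,
    sub_signatures = sub_signatures, rna_rates = rna_rates,
    signal_meanlog = expand(adt_signal$meanlog, markers),
    signal_sdlog = expand(adt_signal$sdlog, markers),
    background_meanlog = expand(adt_background$meanlog, markers),
    background_sdlog = expand(adt_background$sdlog, markers),
    planted_de = planted_de, planted_prop_shift = planted_prop_shift,
    doublet_rate = doublet_rate,
    n_tags_per_plate = as.integer(n_tags_per_plate),
    tag_ambient_lambda = tag_ambient_lambda,
    tag_dominant_lambda = tag_dominant_lambda,
    seed = as.integer(seed)), class = "synthetic_config")
}

#' Generate a synthetic CITE-seq cohort with known ground truth
#'
#' Draws singlet cells per participant (cell types from the group's fraction
#' vector), then ADT counts as `round(exp(Normal))` using each marker's
#' signal parameters where the cell's type truly expresses the marker and the
#' shared background parameters otherwise; transcript counts as Poisson with
#' per-(type, gene) rates times planted fold changes; and sample-tag counts
#' with the participant's tag dominant. Doublets are injected by summing two
#' freshly drawn constituent cells from the same plate (hashtag doublets
#' arise within a loading plate); their count is Binomial(singlets,
#' `doublet_rate`).
#'
#' @param config a [synthetic_config()].
#' @return a list with `adt`, `rna`, `tags` ([count_matrix()]s over identical
#'   cells), `cells` (observed per-cell metadata: id, plate), `sample_map`
#'   (plate x tag -> participant, group), `truth` (per-cell true type,
#'   doublet flag and constituents, signatures, planted-effect registry) and
#'   `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  groups <- config$groups
  types <- colnames(config$cell_type_fractions)
  markers <- colnames(config$signatures)
  genes <- colnames(config$rna_rates)
  n_tags <- config$n_tags_per_plate

  # participants: one per group per plate when groups fill a plate evenly
  participants <- data.frame(
    participant = sprintf("P%02d", seq_len(length(groups) * config$n_per_group)),
    group = rep(groups, each = config$n_per_group),
    stringsAsFactors = FALSE)
  np <- nrow(participants)
  # round-robin across groups so each plate holds one participant per group
  ord <- as.vector(matrix(seq_len(np), nrow = length(groups), byrow = TRUE))
  participants <- participants[ord, ]
  if (np %% n_tags != 0)
    stop("invalid config: n_tags_per_plate must divide the participant count")
  participants$plate <- rep(sprintf("plate%02d", seq_len(np / n_tags)),
                            each = n_tags)
  participants$tag <- rep(sprintf("Tag%02d", seq_len(n_tags)),
                          times = np / n_tags)
  rownames(participants) <- participants$participant

  n_singlet <- np * config$cells_per_participant

  # --- latent cell assignment -------------------------------------------
  sg_part <- with_seed(substream_seed(config$seed, "types"), {
    part <- rep(participants$participant, each = config$cells_per_participant)
    type <- character(n_singlet)
    for (p in participants$participant) {
      idx <- which(part == p)
      g <- participants[p, "group"]
      type[idx] <- sample(types, length(idx), replace = TRUE,
                          prob = config$cell_type_fractions[g, ])
    }
    list(part = part, type = type)
  })

  n_doublet <- with_seed(substream_seed(config$seed, "doublets"),
                         rbinom(1L, n_singlet, config$doublet_rate))
  db <- with_seed(substream_seed(config$seed, "doublet-pairs"), {
    if (n_doublet == 0L)
      list(p1 = character(0), p2 = character(0),
           t1 = character(0), t2 = character(0))
    else {
      plate <- sample(participants$plate, n_doublet, replace = TRUE)
      pick <- function(pl) sample(participants$participant[
        participants$plate == pl], 2L, replace = TRUE)
      pr <- vapply(plate, pick, character(2))
      t_of <- function(p) {
        g <- participants[p, "group"]
        vapply(g, function(gg) sample(types, 1L,
               prob = config$cell_type_fractions[gg, ]), character(1))
      }
      list(p1 = unname(pr[1L, ]), p2 = unname(pr[2L, ]),
           t1 = unname(t_of(pr[1L, ])), t2 = unname(t_of(pr[2L, ])))
    }
  })

  # latent profiles: singlets followed by the 2 x n_doublet constituents
  lat_part <- c(sg_part$part, db$p1, db$p2)
  lat_type <- c(sg_part$type, db$t1, db$t2)
  lat_group <- participants[lat_part, "group"]
  n_latent <- length(lat_part)

  # --- ADT ---------------------------------------------------------------
  adt <- with_seed(substream_seed(config$seed, "adt"), {
    m <- matrix(0, n_latent, length(markers))
    pos <- config$signatures[lat_type, , drop = FALSE]
    # sub-signature markers: positive in only a fraction of the type's cells
    for (ty in names(config$sub_signatures)) {
      fr <- config$sub_signatures[[ty]]
      in_ty <- lat_type == ty
      for (mk in names(fr))
        pos[in_ty, mk] <- runif(sum(in_ty)) < fr[[mk]]
    }
    for (j in seq_along(markers)) {
      mu <- ifelse(pos[, j], config$signal_meanlog[j],
                   config$background_meanlog[j])
      sdl <- ifelse(pos[, j], config$signal_sdlog[j],
                    config$background_sdlog[j])
      m[, j] <- round(exp(rnorm(n_latent, mu, sdl)))
    }
    m
  })

  # --- RNA ---------------------------------------------------------------
  rna <- with_seed(substream_seed(config$seed, "rna"), {
    rates <- config$rna_rates[lat_type, , drop = FALSE]
    if (nrow(config$planted_de)) {
      for (i in seq_len(nrow(config$planted_de))) {
        e <- config$planted_de[i, ]
        hit <- lat_type == e$type & lat_group == e$group
        rates[hit, e$gene] <- rates[hit, e$gene] * 2^e$lfc
      }
    }
    matrix(rpois(length(rates), rates), n_latent, length(genes))
  })

  # --- sample tags -------------------------------------------------------
  tags <- with_seed(substream_seed(config$seed, "tags"), {
    dom <- match(participants[lat_part, "tag"], sprintf("Tag%02d", seq_len(n_tags)))
    m <- matrix(rpois(n_latent * n_tags, config$tag_ambient_lambda),
                n_latent, n_tags)
    m[cbind(seq_len(n_latent), dom)] <-
      rpois(n_latent, config$tag_dominant_lambda)
    m
  })

  # --- merge doublets ----------------------------------------------------
  i1 <- n_singlet + seq_len(n_doublet)
  i2 <- n_singlet + n_doublet + seq_len(n_doublet)
  merge2 <- function(m) rbind(m[seq_len(n_singlet), , drop = FALSE],
                              m[i1, , drop = FALSE] + m[i2, , drop = FALSE])
  adt <- merge2(adt); rna <- merge2(rna); tags <- merge2(tags)
  n_cells <- n_singlet + n_doublet
  ids <- sprintf("cell%06d", seq_len(n_cells))

  truth_cells <- data.frame(
    cell_id = ids,
    participant = c(sg_part$part, db$p1),
    participant2 = c(rep(NA_character_, n_singlet), db$p2),
    group = participants[c(sg_part$part, db$p1), "group"],
    plate = participants[c(sg_part$part, db$p1), "plate"],
    true_type = c(sg_part$type, rep("doublet", n_doublet)),
    type1 = c(sg_part$type, db$t1),
    type2 = c(rep(NA_character_, n_singlet), db$t2),
    is_doublet = c(rep(FALSE, n_singlet), rep(TRUE, n_doublet)),
    stringsAsFactors = FALSE)

  # shuffle cell order so row position never leaks doublet status
  perm <- with_seed(substream_seed(config$seed, "shuffle"),
                    sample.int(n_cells))
  adt <- adt[perm, , drop = FALSE]; rna <- rna[perm, , drop = FALSE]
  tags <- tags[perm, , drop = FALSE]
  truth_cells <- truth_cells[perm, ]
  truth_cells$cell_id <- ids            # ids follow emission order
  rownames(truth_cells) <- ids
  dimnames(adt) <- list(ids, markers)
  dimnames(rna) <- list(ids, genes)
  dimnames(tags) <- list(ids, sprintf("Tag%02d", seq_len(n_tags)))

  list(
    adt = count_matrix(adt, "ADT"),
    rna = count_matrix(rna, "RNA"),
    tags = count_matrix(tags, "TAG"),
    cells = data.frame(cell_id = ids, plate = truth_cells$plate,
                       stringsAsFactors = FALSE),
    sample_map = participants[, c("plate", "tag", "participant", "group")],
    truth = list(cells = truth_cells, signatures = config$signatures,
                 sub_signatures = config$sub_signatures,
                 planted_de = config$planted_de,
                 planted_prop_shift = config$planted_prop_shift,
                 n_singlet = n_singlet, n_doublet = n_doublet,
                 config_hash = config_hash(unclass(config))),
    config = config)
}

#' Summarize the effects planted in a synthetic cohort
#'
#' @param truth the `truth` element of a [generate_cohort()] result.
#' @return a data.frame with one row per planted effect: `effect`
#'   (`"de"` or `"proportion_shift"`), `target`, `type`, `group`, `value`
#'   (log2 fold change or multiplier).
#' @export
truth_report <- function(truth) {
  de <- truth$planted_de
  ps <- truth$planted_prop_shift
  rows <- list()
  if (!is.null(de) && nrow(de))
    rows$de <- data.frame(effect = "de", target = de$gene, type = de$type,
                          group = de$group, value = de$lfc,
                          stringsAsFactors = FALSE)
  if (!is.null(ps) && nrow(ps))
    rows$ps <- data.frame(effect = "proportion_shift", target = ps$type,
                          type = ps$type, group = ps$group,
                          value = ps$multiplier, stringsAsFactors = FALSE)
  if (!length(rows))
    return(data.frame(effect = character(0), target = character(0),
                      type = character(0), group = character(0),
                      value = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
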