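#' Read a per-cell methylation call file and binarise states
#'
#' Single-cell bisulfite calls are predominantly binary; CpGs with an exact
#' 50% methylation level (hemi-methylated sites, one allele of two) are
#' ambiguous and are dropped before downstream analysis. For the remaining
#' sites the binary state is the rounded ratio of methylated to total reads.
#'
#' Three tab-separated dialects are supported:
#' * `counts`: `chromosome  position  met_reads  total_reads`
#'   (Bismark-coverage style; duplicate positions have their read counts
#'   summed before binarisation, treating them as split count lines),
#' * `rates`: `chromosome  position  rate` (duplicates averaged),
#' * `binary`: `chromosome  position  state` (duplicates averaged, so a
#'   0/1 conflict at one position becomes a 0.5 rate and is dropped).
#'
#' @param path Path to a tab-separated file without header.
#' @param dialect One of `"counts"`, `"rates"`, `"binary"`.
#' @return A tibble with columns `chromosome`, `position`, `rate`, `state`
#'   (integer 0/1), sorted by (chromosome, position). Input genomic
#'   positions are taken to be 1-based inclusive.
#' @export
read_cell_calls <- function(path, dialect = c("counts", "rates", "binary")) {
  dialect <- match.arg(dialect)
  cols <- switch(dialect,
    counts = list(names = c("chromosome", "position", "met_reads",
                            "total_reads"),
                  types = "ciii"),
    rates  = list(names = c("chromosome", "position", "rate"),
                  types = "cid"),
    binary = list(names = c("chromosome", "position", "state"),
                  types = "cii")
  )
  raw <- suppressWarnings(
    readr::read_tsv(path, col_names = cols$names,
                    col_types = cols$types, progress = FALSE)
  ) # parse problems are re-raised as errors with line numbers below
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    stop(sprintf("parse error in '%s' at line %d: expected %s, got '%s'",
                 path, probs$row[1], probs$expected[1], probs$actual[1]),
         call. = FALSE)
  }
  if (anyNA(raw)) {
    bad <- which(!stats::complete.cases(raw))[1]
    stop(sprintf("parse error in '%s' at line %d: missing field",
                 path, bad), call. = FALSE)
  }
  if (dialect == "counts") {
    if (any(raw$total_reads < 1)) {
      stop("total_reads must be >= 1", call. = FALSE)
    }
    if (any(raw$met_reads > raw$total_reads) || any(raw$met_reads < 0)) {
      stop("met_reads must be between 0 and total_reads", call. = FALSE)
    }
    raw <- raw |>
      dplyr::group_by(.data$chromosome, .data$position) |>
      dplyr::summarise(met_reads = sum(.data$met_reads),
                       total_reads = sum(.data$total_reads),
                       .groups = "drop") |>
      dplyr::mutate(rate = .data$met_reads / .data$total_reads)
  } else {
    if (dialect == "binary" && !all(raw$state %in% c(0L, 1L))) {
      stop("binary states must be 0 or 1", call. = FALSE)
    }
    if (dialect == "binary") raw$rate <- as.numeric(raw$state)
    if (any(raw$rate < 0 | raw$rate > 1)) {
      stop("rates must lie in [0, 1]", call. = FALSE)
    }
    raw <- raw |>
      dplyr::group_by(.data$chromosome, .data$position) |>
      dplyr::summarise(rate = mean(.data$rate), .groups = "drop")
  }
  raw |>
    dplyr::filter(.data$rate != 0.5) |>
    dplyr::mutate(state = as.integer(.data$rate > 0.5)) |>
    dplyr::arrange(.data$chromosome, .data$position)
}

#' Read genomic region annotations
#'
#' Two formats are supported: BED6 (0-based half-open, converted to 1-based
#' inclusive at this boundary) and a tab-separated TSS table
#' `chromosome  anchor  strand  region_id` whose regions are `anchor +/-
#' window`. For BED the anchor is the interval midpoint (or the 5' end when
#' `anchor = "start"`).
#'
#' @param path Annotation file path.
#' @param format `"bed"` or `"tss"`.
#' @param window Half-width in bp; required for `"tss"`, optional for
#'   `"bed"` (re-centres intervals around the anchor when given).
#' @param anchor For BED input, `"center"` or `"start"` (strand-aware 5'
#'   end).
#' @return A tibble with columns `region_id`, `chromosome`, `start`, `end`,
#'   `strand`, `anchor`, `window` (NA for pure interval regions).
#' @export
read_region_annotations <- function(path, format = c("bed", "tss"),
                                    window = NULL,
                                    anchor = c("center", "start")) {
  format <- match.arg(format)
  anchor <- match.arg(anchor)
  if (!is.null(window) && window <= 0) {
    stop("`window` must be positive", call. = FALSE)
  }
  if (format == "tss") {
    if (is.null(window)) {
      stop("`window` is required for TSS annotations", call. = FALSE)
    }
    tab <- readr::read_tsv(
      path, col_names = c("chromosome", "anchor", "strand", "region_id"),
      col_types = "cicc", progress = FALSE
    )
    ann <- tibble::tibble(
      region_id = tab$region_id,
      chromosome = tab$chromosome,
      start = tab$anchor - as.integer(window),
      end = tab$anchor + as.integer(window),
      strand = tab$strand,
      anchor = tab$anchor,
      window = as.numeric(window)
    )
  } else {
    tab <- readr::read_tsv(
      path,
      col_names = c("chromosome", "start", "end", "region_id", "score",
                    "strand"),
      col_types = "ciiccc", progress = FALSE
    )
    # BED is 0-based half-open; convert to 1-based inclusive
    start1 <- tab$start + 1L
    end1 <- tab$end
    anc <- if (anchor == "center") {
      floor((start1 + end1) / 2)
    } else {
      ifelse(tab$strand == "-", end1, start1)
    }
    if (is.null(window)) {
      ann <- tibble::tibble(region_id = tab$region_id,
                            chromosome = tab$chromosome,
                            start = start1, end = end1,
                            strand = tab$strand, anchor = anc,
                            window = NA_real_)
    } else {
      ann <- tibble::tibble(region_id = tab$region_id,
                            chromosome = tab$chromosome,
                            start = anc - as.integer(window),
                            end = anc + as.integer(window),
                            strand = tab$strand, anchor = anc,
                            window = as.numeric(window))
    }
  }
  if (!all(ann$strand %in% c("+", "-", ".", "*"))) {
    stop("strand must be one of '+', '-', '.', '*'", call. = FALSE)
  }
  if (any(duplicated(ann$region_id))) {
    stop("duplicated region_id in annotations", call. = FALSE)
  }
  ann
}

#' Map binarised calls into annotated regions with scaled coordinates
#'
#' CpGs falling inside an annotated region are assigned a relative position:
#' `(position - anchor) / window` for windowed regions, or an affine map of
#' the interval onto `[-1, 1]` otherwise. Minus-strand regions have the
#' relative position negated so profiles always read 5' to 3'. CpGs outside
#' all regions are discarded.
#'
#' @param calls A tibble of binarised calls with columns `cell`,
#'   `chromosome`, `position`, `state` (e.g. several [read_cell_calls()]
#'   outputs bound together with a `cell` column).
#' @param annotations A tibble as returned by [read_region_annotations()],
#'   or with the same columns.
#' @param window Optional half-width in bp applied to every annotation
#'   (overrides the per-annotation `window` column).
#' @return A methylome dataset: a tibble with columns `cell`, `region`,
#'   `pos` (scaled to `[-1, 1]`), `state`, sorted and unique per
#'   (cell, region, pos). Cell and region universes are carried in the
#'   `cells` / `regions` attributes.
#' @export
build_regions <- function(calls, annotations, window = NULL) {
  stopifnot(all(c("cell", "chromosome", "position", "state") %in%
                  names(calls)))
  if (nrow(annotations) == 0) {
    stop("empty annotation list", call. = FALSE)
  }
  if (!is.null(window)) {
    if (window <= 0) stop("`window` must be positive", call. = FALSE)
    annotations <- annotations |>
      dplyr::mutate(start = .data$anchor - window,
                    end = .data$anchor + window,
                    window = as.numeric(window))
  }
  if (!"window" %in% names(annotations)) annotations$window <- NA_real_
  stopifnot(all(annotations$start < annotations$end),
            all(annotations$anchor >= annotations$start),
            all(annotations$anchor <= annotations$end))

  mapped <- calls |>
    dplyr::inner_join(
      annotations |>
        dplyr::select("region_id", "chromosome", "start", "end", "strand",
                      "anchor", "window"),
      by = "chromosome", relationship = "many-to-many"
    ) |>
    dplyr::filter(.data$position >= .data$start,
                  .data$position <= .data$end) |>
    dplyr::mutate(
      pos = dplyr::if_else(
        is.na(.data$window),
        2 * (.data$position - .data$start) /
          (.data$end - .data$start) - 1,
        (.data$position - .data$anchor) / .data$window
      ),
      pos = dplyr::if_else(.data$strand == "-", -.data$pos, .data$pos)
    ) |>
    dplyr::transmute(cell = .data$cell, region = .data$region_id,
                     pos = .data$pos, state = as.integer(.data$state)) |>
    dplyr::distinct(.data$cell, .data$region, .data$pos,
                    .keep_all = TRUE) |>
    dplyr::arrange(.data$cell, .data$region, .data$pos)
  as_meth_dataset(mapped, cells = unique(calls$cell),
                  regions = annotations$region_id)
}

#' Tag a CpG table as a methylome dataset
#'
#' A methylome dataset is an ordinary tibble with one row per observed CpG
#' (`cell`, `region`, `pos` in `[-1, 1]`, binary `state`) plus `cells` and
#' `regions` attributes recording the full cell/region universe (a cell may
#' cover no region at all and still exist).
#'
#' @param data A data frame with the four columns above.
#' @param cells,regions Optional universes; default to the distinct values
#'   present in `data`.
#' @return The validated tibble with attributes set.
#' @export
as_meth_dataset <- function(data, cells = NULL, regions = NULL) {
  stopifnot(all(c("cell", "region", "pos", "state") %in% names(data)))
  data <- tibble::as_tibble(data)
  if (nrow(data)) {
    stopifnot(all(data$state %in% c(0L, 1L)),
              all(data$pos >= -1 - 1e-9), all(data$pos <= 1 + 1e-9))
  }
  attr(data, "cells") <- as.character(cells %||% unique(data$cell))
  attr(data, "regions") <- as.character(regions %||% unique(data$region))
  data
}

dataset_cells <- function(data) {
  attr(data, "cells") %||% unique(data$cell)
}

dataset_regions <- function(data) {
  attr(data, "regions") %||% unique(data$region)
}

#' Filter regions by cross-cell coverage and variability
#'
#' A cell *covers* a region iff it has at least `min_cpgs` observed CpGs
#' there. A region is retained iff it is covered by at least
#' `min_cell_frac` of all cells and (optionally) the per-cell mean
#' methylation rates of the covering cells are not all equal — homogeneous
#' regions carry no information about sub-population structure.
#'
#' @param data A methylome dataset tibble (`cell`, `region`, `pos`,
#'   `state`).
#' @param min_cell_frac Minimum fraction of cells that must cover a region
#'   (default 0.5).
#' @param min_cpgs Minimum CpGs for a cell to count as covering a region
#'   (default 10; interpreted per cell per region).
#' @param require_variability Drop regions whose covering cells all have
#'   exactly equal mean rates (default TRUE).
#' @return The dataset restricted to retained regions (same columns).
#' @export
filter_regions <- function(data, min_cell_frac = 0.5, min_cpgs = 10,
                           require_variability = TRUE) {
  stopifnot(min_cell_frac > 0, min_cell_frac <= 1, min_cpgs >= 1)
  n_cells <- length(dataset_cells(data))
  per <- data |>
    dplyr::group_by(.data$cell, .data$region) |>
    dplyr::summarise(n_cpgs = dplyr::n(), mean_rate = mean(.data$state),
                     .groups = "drop")
  region_stats <- per |>
    dplyr::filter(.data$n_cpgs >= min_cpgs) |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(
      n_covering = dplyr::n(),
      variable = dplyr::n_distinct(.data$mean_rate) > 1,
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_covering >= min_cell_frac * n_cells)
  if (require_variability) {
    region_stats <- dplyr::filter(region_stats, .data$variable)
  }
  keep <- region_stats$region
  if (length(keep) == 0) {
    stop(sprintf(
      "all %d regions removed by filtering (min_cell_frac = %g, min_cpgs = %d, require_variability = %s)",
      length(dataset_regions(data)), min_cell_frac, min_cpgs,
      require_variability
    ), call. = FALSE)
  }
  out <- dplyr::filter(data, .data$region %in% keep)
  as_meth_dataset(out, cells = dataset_cells(data), regions = keep)
}

#' Split CpGs into training and test sets
#'
#' Within every (cell, region) block the observed CpGs are partitioned
#' uniformly at random: `round(train_fraction * I)` go to training (at
#' least one whenever the block is non-empty), the remainder to test. The
#' split is reproducible from the seed and the union of the two parts
#' reconstructs the input exactly.
#'
#' @param data A methylome dataset tibble.
#' @param train_fraction Fraction of CpGs per block used for training
#'   (default 0.5).
#' @param seed Integer seed for the split.
#' @return A list with elements `train` and `test`, both methylome
#'   datasets with the same cell/region universes as the input.
#' @export
split_train_test <- function(data, train_fraction = 0.5, seed = 1) {
  stopifnot(train_fraction > 0, train_fraction <= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  u <- stats::runif(nrow(data))
  grp <- paste(data$cell, data$region, sep = "\r")
  # rank CpGs within each block by the random draw; the first
  # round(f * I) (>= 1) ranks train
  ord <- order(grp, u)
  rle_g <- rle(grp[ord])
  block_n <- rle_g$lengths
  n_train <- pmax(1L, as.integer(round(train_fraction * block_n)))
  within_rank <- sequence(block_n)
  is_train_sorted <- within_rank <= rep(n_train, block_n)
  is_train <- logical(nrow(data))
  is_train[ord] <- is_train_sorted
  cells <- dataset_cells(data)
  regions <- dataset_regions(data)
  list(
    train = as_meth_dataset(data[is_train, , drop = FALSE], cells, regions),
    test = as_meth_dataset(data[!is_train, , drop = FALSE], cells, regions)
  )
}

#' Write / read a methylome dataset directory
#'
#' The on-disk layout is one tab-separated file per cell
#' (`cells/<cell>.tsv` with columns `region`, `pos`, `state`) plus a JSON
#' manifest listing cells, regions and any provenance notes. Synthetic and
#' real datasets share this layout.
#'
#' @param data A methylome dataset tibble.
#' @param dir Output/input directory.
#' @param extra Optional named list merged into the manifest (e.g. filters
#'   applied, generator config).
#' @return `write_meth_dataset()` returns `dir` invisibly;
#'   `read_meth_dataset()` returns the dataset tibble.
#' @export
write_meth_dataset <- function(data, dir, extra = list()) {
  cell_dir <- file.path(dir, "cells")
  dir.create(cell_dir, recursive = TRUE, showWarnings = FALSE)
  cells <- dataset_cells(data)
  for (cl in cells) {
    d <- data[data$cell == cl, c("region", "pos", "state")]
    readr::write_tsv(d, file.path(cell_dir, paste0(cl, ".tsv")),
                     progress = FALSE)
  }
  manifest <- c(list(cells = cells, regions = dataset_regions(data),
                     n_cpgs = nrow(data)), extra)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_meth_dataset
#' @export
read_meth_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  cells <- as.character(manifest$cells)
  parts <- lapply(cells, function(cl) {
    path <- file.path(dir, "cells", paste0(cl, ".tsv"))
    d <- readr::read_tsv(path, col_types = "cdi", progress = FALSE)
    if (nrow(d)) d$cell <- cl else d$cell <- character(0)
    d
  })
  out <- dplyr::bind_rows(parts)
  if (nrow(out) == 0) {
    out <- tibble::tibble(cell = character(), region = character(),
                          pos = double(), state = integer())
  }
  out <- dplyr::select(out, "cell", "region", "pos", "state") |>
    dplyr::arrange(.data$cell, .data$region, .data$pos)
  as_meth_dataset(out, cells = cells,
                  regions = as.character(manifest$regions))
}
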