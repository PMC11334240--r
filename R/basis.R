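#' Reference tissue basis
#'
#' An ordered collection of [tissue()] objects with per-tissue provenance
#' tags. Order matters: it defines the tie-break of the nearest-reference
#' assignment downstream (lowest index wins).
#'
#' @param tissues List of [tissue()] objects with unique names.
#' @param provenance Character vector of per-tissue source tags (recycled
#'   if length 1; default `"base-set"`).
#' @return An object of class `tissue_basis`.
#' @export
tissue_basis <- function(tissues, provenance = "base-set") {
  stopifnot(is.list(tissues), length(tissues) >= 1L,
            all(vapply(tissues, is_tissue, TRUE)))
  nm <- vapply(tissues, `[[`, "", "name")
  if (anyDuplicated(nm))
    stop("duplicate tissue names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  provenance <- rep_len(provenance, length(tissues))
  structure(list(tissues = tissues, provenance = provenance),
            class = "tissue_basis")
}

#' @export
print.tissue_basis <- function(x, ...) {
  cat("<tissue_basis> ", length(x$tissues), " tissues (",
      paste(names(table(x$provenance)), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' @export
length.tissue_basis <- function(x) length(x$tissues)

basis_names <- function(basis) vapply(basis$tissues, `[[`, "", "name")

#' Expand a tissue basis to cover the full CT-number range
#'
#' Human-tissue tables leave gaps in dual-energy CT-number space: between
#' soft and bony tissues (filled with spongiosa), below lung (filled with
#' lung-air partial-volume mixtures) and at the highest CT numbers (filled
#' with a dense-bone series). This appends, in order: (a) a supplied
#' spongiosa set, (b) `n_low_density` lung-air volumetric mixtures at
#' evenly spaced volume fractions in (0, 1), and (c) a bone series of
#' volumetric cortical-bone/red-marrow mixtures plus a multiplicative
#' density ramp on the densest bone.
#'
#' @param base A [tissue_basis()].
#' @param spongiosa List of [tissue()] objects to append (may be empty).
#' @param n_low_density Number of lung-air mixtures to generate.
#' @param bone_series `NULL` or a list with elements `n_mix` (number of
#'   bone/marrow volumetric mixtures) and `density_ramp` (multiplicative
#'   density factors applied to the densest base bone; default
#'   `seq(1.02, 1.1, length.out = 5)`).
#' @param lung_name,marrow_name Names of the lung and red-marrow entries
#'   in `base` used for the generated mixtures.
#' @param elements Element table.
#' @return The expanded [tissue_basis()]; name collisions are rejected.
#' @export
expand_basis <- function(base, spongiosa = list(), n_low_density = 0,
                         bone_series = NULL, lung_name = "lung",
                         marrow_name = "red_marrow",
                         elements = element_table()) {
  stopifnot(inherits(base, "tissue_basis"))
  tissues <- base$tissues
  prov <- base$provenance

  for (sp in spongiosa) {
    stopifnot(is_tissue(sp))
    tissues <- c(tissues, list(sp))
    prov <- c(prov, "spongiosa-addition")
  }

  if (n_low_density > 0) {
    nm <- basis_names(base)
    if (!lung_name %in% nm)
      stop("lung tissue '", lung_name, "' not in basis", call. = FALSE)
    lung <- base$tissues[[match(lung_name, nm)]]
    air <- air_composition(elements)
    f <- seq_len(n_low_density) / (n_low_density + 1)
    for (i in seq_along(f)) {
      mx <- mix_by_volume(lung, air, f[i],
                          name = sprintf("lung_air_%02d", i),
                          category = "low_density")
      tissues <- c(tissues, list(mx))
      prov <- c(prov, "lung-air-mixture")
    }
  }

  if (!is.null(bone_series)) {
    nm <- basis_names(base)
    cats <- vapply(base$tissues, `[[`, "", "category")
    bones <- which(cats == "bone")
    if (length(bones) == 0L)
      stop("no bone-category tissue in basis for the bone series",
           call. = FALSE)
    dens <- vapply(base$tissues[bones], `[[`, 0, "density")
    cortical <- base$tissues[[bones[which.max(dens)]]]
    if (!marrow_name %in% nm)
      stop("marrow tissue '", marrow_name, "' not in basis", call. = FALSE)
    marrow <- base$tissues[[match(marrow_name, nm)]]
    n_mix <- bone_series$n_mix %||% 0
    if (n_mix > 0) {
      f <- seq_len(n_mix) / (n_mix + 1)
      for (i in seq_along(f)) {
        mx <- mix_by_volume(cortical, marrow, f[i],
                            name = sprintf("bone_marrow_%02d", i),
                            category = "bone")
        tissues <- c(tissues, list(mx))
        prov <- c(prov, "bone-series")
      }
    }
    ramp <- bone_series$density_ramp %||% seq(1.02, 1.1, length.out = 5)
    for (i in seq_along(ramp)) {
      up <- tissue(sprintf("bone_dense_%02d", i), cortical$fractions,
                   cortical$density * ramp[i], "bone")
      tissues <- c(tissues, list(up))
      prov <- c(prov, "bone-series")
    }
  }

  tissue_basis(tissues, prov)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert a tissue basis to a data frame
#'
#' One row per tissue: `name`, `category`, `density_g_cm3`, then one
#' column per element symbol present anywhere in the basis.
#'
#' @param x A [tissue_basis()].
#' @param ... Unused.
#' @return A data frame.
#' @export
as.data.frame.tissue_basis <- function(x, ...) {
  syms <- unique(unlist(lapply(x$tissues, function(t) names(t$fractions))))
  rows <- lapply(x$tissues, function(t) {
    w <- stats::setNames(numeric(length(syms)), syms)
    w[names(t$fractions)] <- t$fractions
    c(list(name = t$name, category = t$category,
           density_g_cm3 = t$density), as.list(w))
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
}

#' Read and write tissue tables
#'
#' CSV layout: columns `name`, `category`, `density_g_cm3`, then one
#' column per element symbol holding weight fractions. A JSON mirror of
#' the same fields is supported; format is chosen from the file
#' extension. Row fraction sums are renormalized when within
#' `renorm_tol` of 1 and rejected otherwise.
#'
#' @param path File path (`.csv` or `.json`).
#' @param provenance Provenance tag(s) for the loaded tissues.
#' @param renorm_tol Maximum closure violation accepted before
#'   renormalization (default 0.02, accommodating rounded published
#'   tables).
#' @param elements Element table (validates symbols).
#' @return `read_tissue_table()` returns a [tissue_basis()];
#'   `write_tissue_table()` returns `path` invisibly.
#' @export
read_tissue_table <- function(path, provenance = "base-set",
                              renorm_tol = 0.02,
                              elements = element_table()) {
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "json") {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  }
  fixed <- c("name", "category", "density_g_cm3")
  if (!all(fixed %in% names(df)))
    stop("tissue table must have columns ", paste(fixed, collapse = ", "),
         call. = FALSE)
  syms <- setdiff(names(df), fixed)
  elem_rows(syms, elements)  # validate symbols early
  tissues <- lapply(seq_len(nrow(df)), function(i) {
    w <- as.numeric(df[i, syms])
    names(w) <- syms
    w <- w[!is.na(w) & w != 0]
    s <- sum(w)
    if (abs(s - 1) > renorm_tol)
      stop("row '", df$name[i], "' fractions sum to ", format(s),
           call. = FALSE)
    tissue(df$name[i], w / s, df$density_g_cm3[i],
           category = df$category[i])
  })
  tissue_basis(tissues, provenance)
}

#' @rdname read_tissue_table
#' @param basis A [tissue_basis()] (or list of [tissue()]) to write.
#' @export
write_tissue_table <- function(basis, path) {
  if (!inherits(basis, "tissue_basis")) basis <- tissue_basis(basis)
  df <- as.data.frame(basis)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(df, path, digits = NA, auto_unbox = FALSE)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Built-in human reference tissue basis
#'
#' Loads the packaged table of published-style human tissue compositions
#' (Woodard-White/ICRU-44 lineage: soft tissues, lung, marrow, cortical
#' bone, plus water and air) shipped under `extdata/`. Spongiosa entries
#' are generated on request as documented trabecular-bone/red-marrow
#' volumetric mixtures (tagged `mixture-derived`) rather than transcribed.
#'
#' @param with_spongiosa Number of generated spongiosa mixtures to append
#'   (0 for the bare base set).
#' @param elements Element table.
#' @return A [tissue_basis()].
#' @export
default_tissue_basis <- function(with_spongiosa = 0,
                                 elements = element_table()) {
  path <- system.file("extdata", "reference_tissues.csv",
                      package = "dectspr", mustWork = TRUE)
  basis <- read_tissue_table(path, provenance = "base-set",
                             elements = elements)
  if (with_spongiosa > 0) {
    nm <- basis_names(basis)
    cortical <- basis$tissues[[match("cortical_bone", nm)]]
    marrow <- basis$tissues[[match("red_marrow", nm)]]
    f <- seq_len(with_spongiosa) / (with_spongiosa + 1)
    sp <- lapply(seq_along(f), function(i)
      mix_by_volume(cortical, marrow, f[i],
                    name = sprintf("spongiosa_%02d", i),
                    category = "spongiosa"))
    basis <- tissue_basis(c(basis$tissues, sp),
                          c(basis$provenance,
                            rep("mixture-derived", length(sp))))
  }
  basis
}
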