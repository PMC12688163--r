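#' Mutation / copy-number channel schemas
#'
#' Canonical channel name lists for the supported schemas. SBS96 channels are
#' generated from the pyrimidine-strand convention; ID83 and allele-specific
#' CN48 channels are defined by data files shipped with the package
#' (`inst/extdata/id83_channels.tsv`, `inst/extdata/cn48_channels.tsv`) so
#' the binning conventions are inspectable and cannot drift from the code.
#'
#' @return Character vector of channel names in canonical order.
#' @export
sbs96_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    ref <- substr(s, 1, 1)
    as.vector(t(outer(bases, bases, function(p5, p3)
      paste0(p5, "[", s, "]", p3))))
  }))
}

schema_file <- function(name) {
  path <- system.file("extdata", name, package = "hrdclass")
  if (path == "") path <- file.path("inst", "extdata", name)  # pre-install use
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname sbs96_channels
#' @export
id83_channel_defs <- function() schema_file("id83_channels.tsv")

#' @rdname sbs96_channels
#' @export
id83_channels <- function() id83_channel_defs()$channel

#' @rdname sbs96_channels
#' @export
cn48_channel_defs <- function() schema_file("cn48_channels.tsv")

#' @rdname sbs96_channels
#' @export
cn48_channels <- function() cn48_channel_defs()$channel

schema_channels <- function(schema_id) {
  switch(schema_id,
         SBS96 = sbs96_channels(),
         ID83 = id83_channels(),
         CN48 = cn48_channels(),
         CX = NULL,  # CX exposures are accepted precomputed; channels free-form
         stop("unknown schema: ", schema_id))
}

#' Signature catalogue
#'
#' A channels x signatures matrix of non-negative weights in which every
#' signature column sums to 1. For the fixed schemas (SBS96, ID83, CN48) the
#' channel names must match the canonical list exactly; channel order is
#' canonicalised on construction.
#'
#' @param weights Numeric matrix, channels in rows (rownames = channel
#'   names), signatures in columns (colnames = signature names).
#' @param schema_id One of `"SBS96"`, `"ID83"`, `"CN48"`, `"CX"`.
#' @return A `signature_catalogue` object.
#' @export
signature_catalogue <- function(weights, schema_id) {
  weights <- as.matrix(weights)
  if (any(weights < 0)) stop("negative signature weight")
  chans <- schema_channels(schema_id)
  if (!is.null(chans)) {
    unknown <- setdiff(rownames(weights), chans)
    if (length(unknown) > 0)
      stop("unknown channel name(s) for schema ", schema_id, ": ",
           paste(utils::head(unknown, 3), collapse = ", "))
    if (nrow(weights) != length(chans))
      stop("schema ", schema_id, " needs ", length(chans),
           " channels, got ", nrow(weights))
    weights <- weights[chans, , drop = FALSE]
  }
  sums <- colSums(weights)
  off <- abs(sums - 1) > 1e-3
  if (any(off & sums > 0))
    stop("signature column(s) do not sum to 1 (within 1e-3): ",
         paste(colnames(weights)[off], collapse = ", "))
  ok <- sums > 0
  weights[, ok] <- sweep(weights[, ok, drop = FALSE], 2, sums[ok], "/")
  structure(weights, schema_id = schema_id,
            class = c("signature_catalogue", "matrix", "array"))
}

catalogue_schema <- function(x) attr(x, "schema_id")

#' Read a COSMIC-style signature catalogue
#'
#' Tab-delimited matrix with channel names in the first column and one
#' column per signature. Columns are renormalised to sum exactly 1 if they
#' are within 1e-3 of 1, otherwise an error is raised.
#'
#' @param path Path to the file.
#' @param schema_id Schema of the catalogue (see [signature_catalogue()]).
#' @return A `signature_catalogue`.
#' @export
read_signature_catalogue <- function(path, schema_id) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  signature_catalogue(m, schema_id)
}

#' @rdname read_signature_catalogue
#' @param x A `signature_catalogue` to write.
#' @export
write_signature_catalogue <- function(x, path) {
  df <- data.frame(channel = rownames(x), unclass(x), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Synthetic signature catalogue
#'
#' Builds a random but reproducible catalogue for a schema: each signature
#' concentrates most of its weight on a few characteristic channels (sparse
#' Dirichlet-like profiles), which makes refitting well-posed in tests and
#' simulations. This is a synthetic stand-in for reference catalogues such as
#' COSMIC, which are not redistributed with the package.
#'
#' @param schema_id Schema (see [signature_catalogue()]).
#' @param signature_names Names of the signatures to generate.
#' @param seed Integer seed.
#' @param peak_channels Number of high-weight channels per signature.
#' @return A `signature_catalogue`.
#' @export
synthetic_signature_catalogue <- function(schema_id, signature_names,
                                          seed = 1, peak_channels = 6) {
  chans <- schema_channels(schema_id)
  if (is.null(chans)) stop("synthetic catalogue needs a fixed-channel schema")
  n <- length(chans)
  rng <- local({ set.seed(seed); NULL })
  set.seed(seed)
  w <- sapply(seq_along(signature_names), function(j) {
    v <- stats::rgamma(n, shape = 0.05)
    peaks <- sample.int(n, peak_channels)
    v[peaks] <- v[peaks] + stats::rgamma(peak_channels, shape = 5)
    v / sum(v)
  })
  rownames(w) <- chans
  colnames(w) <- signature_names
  signature_catalogue(w, schema_id)
}
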