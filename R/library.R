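#' Design a dual-sgRNA library
#'
#' Builds a dual-guide CRISPRi library design: `sgrnas_per_gene` guides per
#' gene plus `n_ntc` non-targeting controls (ntc), with a construct for
#' every ordered pair of sgRNAs over the combined set — including self-pairs
#' and pairings with the controls, so that `S` sgRNAs yield `S^2` constructs
#' before dropout. An optional uniform dropout emulates the small fraction
#' of pairs lost during cloning of large libraries.
#'
#' Non-targeting controls are first-class sgRNAs with the reserved gene
#' label `"ntc"`: constructs pairing a query sgRNA with an ntc measure that
#' query's single-gene phenotype, and ntc-ntc constructs define the
#' normalizer and null distributions used downstream, so at least one ntc
#' is required whenever interaction scoring is intended.
#'
#' @param genes character vector of gene names (must be unique; the name
#'   `"ntc"` is reserved for controls).
#' @param sgrnas_per_gene number of sgRNAs targeting each gene (>= 1).
#' @param n_ntc number of non-targeting control sgRNAs (>= 0).
#' @param dropout_fraction fraction in `[0, 1)` of constructs removed
#'   uniformly at random (cloning attrition).
#' @param seed optional integer making the dropout reproducible; the
#'   caller's RNG state is untouched.
#' @return A `gi_library` object: a list with data frames `sgrnas`
#'   (`sgrna_id`, `gene`, `is_ntc`) and `constructs` (`construct_id`,
#'   `sgrna_a`, `sgrna_b`; position A is the first cassette position).
#' @examples
#' lib <- make_library(paste0("G", 1:10), sgrnas_per_gene = 2, n_ntc = 3)
#' nrow(lib$constructs) # 23^2 = 529
#' @export
make_library <- function(genes, sgrnas_per_gene = 2L, n_ntc = 13L,
                         dropout_fraction = 0, seed = NULL) {
  genes <- as.character(genes)
  if (length(genes) == 0L) stop("'genes' must be non-empty")
  if (anyDuplicated(genes)) stop("duplicate gene names are not allowed")
  if ("ntc" %in% genes) stop("the gene name 'ntc' is reserved for controls")
  if (any(grepl("[|:]", genes)))
    stop("gene names must not contain '|' or ':'")
  if (sgrnas_per_gene < 1L) stop("'sgrnas_per_gene' must be >= 1")
  if (n_ntc < 0L) stop("'n_ntc' must be >= 0")
  if (dropout_fraction < 0 || dropout_fraction >= 1)
    stop("'dropout_fraction' must be in [0, 1)")

  sg <- data.frame(
    sgrna_id = c(
      paste0(rep(genes, each = sgrnas_per_gene), "-sg",
             rep(seq_len(sgrnas_per_gene), length(genes))),
      if (n_ntc > 0L) paste0("ntc-", seq_len(n_ntc))
    ),
    gene = c(rep(genes, each = sgrnas_per_gene), rep("ntc", n_ntc)),
    stringsAsFactors = FALSE
  )
  sg$is_ntc <- sg$gene == "ntc"

  ids <- sg$sgrna_id
  con <- expand.grid(sgrna_b = ids, sgrna_a = ids,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  con <- con[, c("sgrna_a", "sgrna_b")]
  con$construct_id <- paste(con$sgrna_a, con$sgrna_b, sep = ":")

  n_drop <- floor(dropout_fraction * nrow(con))
  if (n_drop > 0L) {
    drop <- with_seed(seed, sample.int(nrow(con), n_drop))
    con <- con[-drop, ]
  }
  rownames(con) <- NULL

  lib <- structure(
    list(sgrnas = sg, constructs = con[, c("construct_id", "sgrna_a", "sgrna_b")]),
    class = "gi_library"
  )
  if (n_ntc > 0L && !any(lib$constructs$sgrna_a %in% ntc_ids(lib) &
                         lib$constructs$sgrna_b %in% ntc_ids(lib)))
    warning("dropout removed every ntc-ntc construct; ",
            "phenotype normalization will be impossible")
  lib
}

ntc_ids <- function(library) library$sgrnas$sgrna_id[library$sgrnas$is_ntc]

## gene lookup: named character vector sgrna_id -> gene
gene_of <- function(library) {
  stats::setNames(library$sgrnas$gene, library$sgrnas$sgrna_id)
}

#' @export
print.gi_library <- function(x, ...) {
  n_ntc <- sum(x$sgrnas$is_ntc)
  cat(sprintf(
    "Dual-sgRNA library: %d sgRNAs (%d genes + %d ntc), %d constructs\n",
    nrow(x$sgrnas), length(unique(x$sgrnas$gene[!x$sgrnas$is_ntc])),
    n_ntc, nrow(x$constructs)))
  invisible(x)
}

#' Write or read a library design as TSV
#'
#' Two plain tab-separated files are written next to `prefix`:
#' `<prefix>_sgrnas.tsv` (`sgrna_id  gene  is_ntc`) and
#' `<prefix>_constructs.tsv` (`construct_id  sgrna_a  sgrna_b`).
#'
#' @param library a `gi_library` object.
#' @param prefix path prefix for the two files.
#' @return `write_library()` returns the two paths invisibly;
#'   `read_library()` returns a `gi_library`.
#' @export
write_library <- function(library, prefix) {
  stop_if_not_class(library, "gi_library", "library")
  paths <- paste0(prefix, c("_sgrnas.tsv", "_constructs.tsv"))
  utils::write.table(library$sgrnas, paths[1], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(library$constructs, paths[2], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' @rdname write_library
#' @export
read_library <- function(prefix) {
  sg <- utils::read.delim(paste0(prefix, "_sgrnas.tsv"),
                          stringsAsFactors = FALSE)
  con <- utils::read.delim(paste0(prefix, "_constructs.tsv"),
                           stringsAsFactors = FALSE)
  sg$is_ntc <- as.logical(sg$is_ntc)
  bad <- setdiff(unique(c(con$sgrna_a, con$sgrna_b)), sg$sgrna_id)
  if (length(bad))
    stop("constructs reference unknown sgRNAs: ", paste(bad, collapse = ", "))
  structure(list(sgrnas = sg, constructs = con), class = "gi_library")
}
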