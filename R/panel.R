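#' Load a virtual gene panel
#'
#' Reads a plain-text panel file: one HGNC symbol per line, optionally
#' followed by a tab and an inheritance token (`AR` or `XL`); `#` starts a
#' comment. Symbols are upper-cased and deduplicated. The panel plays the
#' role of a virtual panel carved out of a larger diagnostic exome: variants
#' outside it are ignored in panel mode, while exome (WES) mode skips the
#' restriction entirely.
#'
#' @param path panel file path.
#' @param name panel name; defaults to the file name.
#' @return an object of class `gene_panel`: list with `name`, `genes`
#'   (character vector) and `inheritance` (named character vector, possibly
#'   empty, values `"AR"`/`"XL"`).
#' @export
load_panel <- function(path, name = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines_kept <- which(lines != "")
  if (length(lines_kept) == 0)
    stop("panel file '", path, "' contains no gene symbols")
  genes <- character(0)
  inh <- character(0)
  for (i in lines_kept) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    sym <- toupper(trimws(fields[1]))
    if (length(fields) >= 2 && trimws(fields[2]) != "") {
      tok <- toupper(trimws(fields[2]))
      if (!tok %in% c("AR", "XL"))
        stop("malformed inheritance token '", fields[2], "' at line ", i,
             " of ", path)
      inh[sym] <- tok
    }
    genes <- c(genes, sym)
  }
  structure(list(name = name, genes = sort(unique(genes)),
                 inheritance = inh),
            class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  cat("Gene panel '", x$name, "': ", length(x$genes), " genes",
      sep = "")
  if (length(x$inheritance))
    cat(" (", sum(x$inheritance == "AR"), " AR, ",
        sum(x$inheritance == "XL"), " XL annotated)", sep = "")
  cat("\n")
  invisible(x)
}

#' Restrict records to a gene panel
#'
#' Keeps exactly the records whose gene symbol is in the panel, preserving
#' order. Idempotent.
#'
#' @param records a record table.
#' @param panel a `gene_panel` from [load_panel()].
#' @return the filtered record table.
#' @export
restrict_to_panel <- function(records, panel) {
  stopifnot(inherits(panel, "gene_panel"))
  records[toupper(records$gene) %in% panel$genes, , drop = FALSE]
}

#' X-linked genes of a panel
#'
#' @param panel a `gene_panel`.
#' @return character vector of genes annotated `XL` (possibly empty).
#' @export
panel_xl_genes <- function(panel) {
  names(panel$inheritance)[panel$inheritance == "XL"]
}
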