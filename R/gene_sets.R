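#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one set per line, tab-delimited, `name<TAB>description<TAB>`
#' followed by member symbols. Duplicate members within a line are collapsed;
#' symbols are whitespace-stripped and matched case-sensitively.
#'
#' @param path File path.
#' @param ir_name Optional name of the set to designate as the
#'   inflammatory-response (IR) set; must resolve to a set in the file.
#' @return A named list of character vectors with class
#'   `gene_set_collection`; the designated IR set name (if any) is stored in
#'   the `ir_name` attribute.
#' @export
read_gene_sets <- function(path, ir_name = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- trimws(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    if (length(fields) < 3) {
      stop(sprintf("GMT line %d has %d field(s); need name, description and at least one member",
                   i, length(fields)), call. = FALSE)
    }
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0) {
      stop(sprintf("GMT line %d (\"%s\") has no non-empty members",
                   i, fields[1]), call. = FALSE)
    }
    sets[[fields[1]]] <- members
  }
  gene_set_collection(sets, ir_name = ir_name)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors of gene symbols.
#' @param ir_name Optional name of the inflammatory-response set.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, ir_name = NULL) {
  if (length(sets) > 0 && (is.null(names(sets)) || any(!nzchar(names(sets))))) {
    stop("every gene set must be named", call. = FALSE)
  }
  sets <- lapply(sets, function(m) {
    m <- unique(trimws(as.character(m)))
    m[nzchar(m)]
  })
  if (any(lengths(sets) == 0)) {
    stop("gene sets must contain at least one non-empty symbol", call. = FALSE)
  }
  if (!is.null(ir_name) && !ir_name %in% names(sets)) {
    stop(sprintf("designated IR set \"%s\" not present in the collection",
                 ir_name), call. = FALSE)
  }
  structure(sets, class = "gene_set_collection", ir_name = ir_name)
}

#' Write a gene-set collection as GMT
#'
#' @param sets A `gene_set_collection` or named list of character vectors.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d set(s)\n", length(x)))
  if (!is.null(attr(x, "ir_name"))) {
    cat("IR set:", attr(x, "ir_name"), "\n")
  }
  invisible(x)
}
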