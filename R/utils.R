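## Byte-wise (C locale) ordering so that sorted output is identical across
## platforms and locales regardless of LC_COLLATE.
.radixOrder <- function(...) order(..., method = "radix")

## Exact rendering of base-pair quantities: whole numbers print with no
## decimal point, half-integers (the only other value a center distance can
## take) print with a ".5" suffix. Never scientific notation.
.formatBp <- function(x) {
    out <- character(length(x))
    whole <- x == floor(x)
    out[whole] <- sprintf("%.0f", x[whole])
    out[!whole] <- sprintf("%.1f", x[!whole])
    out
}

## Numeric -> CSV cell: NA becomes the empty string; otherwise R's shortest
## faithful decimal representation (round-trips through as.numeric).
.formatNum <- function(x) {
    out <- as.character(x)
    out[is.na(x)] <- ""
    out
}

## Minimal RFC-4180 field quoting: only fields containing a comma, quote or
## newline are quoted, so canonical files stay byte-stable.
.csvField <- function(x) {
    x <- as.character(x)
    x[is.na(x)] <- ""
    needs <- grepl('[",\n\r]', x)
    x[needs] <- paste0('"', gsub('"', '""', x[needs], fixed = TRUE), '"')
    x
}

## Assemble CSV text from a list of already-formatted character columns and
## write it with "\n" line endings (byte-identical across platforms).
.writeCsv <- function(cols, header, path) {
    stopifnot(length(cols) == length(header))
    lines <- paste(header, collapse = ",")
    if (length(cols[[1]]) > 0L) {
        body <- do.call(paste, c(lapply(cols, .csvField), sep = ","))
        lines <- c(lines, body)
    }
    con <- tryCatch(file(path, open = "wb"),
                    error = function(e) stop("cannot write to '", path, "': ",
                                             conditionMessage(e), call. = FALSE))
    on.exit(close(con))
    writeLines(lines, con, sep = "\n")
    invisible(NULL)
}

.pasteKey <- function(...) paste(..., sep = "\r")
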