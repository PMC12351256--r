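# shared validation helpers

validate_data_table <- function(data, min_rows = 1L) {
  if (is.matrix(data)) data <- as.data.frame(data)
  if (!is.data.frame(data)) stop("expected a data frame of numeric columns")
  if (is.null(names(data)) || any(!nzchar(names(data)))) {
    stop("all columns must be named")
  }
  not_num <- names(data)[!vapply(data, is.numeric, logical(1))]
  if (length(not_num) > 0L) {
    stop("non-numeric columns: ", paste(not_num, collapse = ", "))
  }
  has_na <- names(data)[vapply(data, function(x) anyNA(x), logical(1))]
  if (length(has_na) > 0L) {
    stop("missing values in columns: ", paste(has_na, collapse = ", "))
  }
  if (nrow(data) < min_rows) {
    stop("need at least ", min_rows, " rows, got ", nrow(data))
  }
  data
}

# read a CSV into a validated numeric table (header row required, NA disallowed)
read_data_table <- function(path) {
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE)
  not_num <- names(df)[!vapply(df, is.numeric, logical(1))]
  if (length(not_num) > 0L) {
    for (nm in not_num) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[nm]]))))[1]
      stop("non-numeric cell in column '", nm, "', data row ",
           if (is.na(bad)) "?" else bad)
    }
  }
  validate_data_table(df)
}

# derive the i-th worker seed from a master seed, staying inside 32-bit range
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + i - 1) %% (.Machine$integer.max - 1L) + 1)
}
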