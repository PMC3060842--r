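# Data-access code generation: introspect a relational table, emit an
# accessor class wrapping INSERT/UPDATE/SELECT/DELETE behind four
# persistence operations (persist, update, retrieve, delete), with all SQL
# hidden from caller code and every value bound as a parameter.
#
# The reference engine is embedded SQLite through DBI; the emitted SQL is
# the common-denominator dialect plus a small shim (identifier quoting and
# last-inserted-key retrieval) noted in the generated source.

sql_type_map <- function(sql_type, column) {
  t <- toupper(trimws(sql_type))
  if (grepl("TIMESTAMP|DATETIME|^DATE$|^TIME$", t)) {
    "timestamp"
  } else if (grepl("INT", t)) {
    "integer"
  } else if (grepl("CHAR|CLOB|TEXT", t)) {
    "text"
  } else if (grepl("BLOB", t) || t == "") {
    "blob"
  } else if (grepl("REAL|FLOA|DOUB|NUMERIC|DECIMAL", t)) {
    "real"
  } else {
    pu_stop(
      "unsupported_type",
      "column \"", column, "\" has unmappable SQL type \"", sql_type, "\""
    )
  }
}

audit_column_names <- c("creationdate", "modificationdate")

#' Construct a table descriptor
#'
#' Usually produced by [introspect()]; exposed so that code can be
#' generated for schemas described by hand.
#'
#' @param table_name table name
#' @param columns data.frame with columns `name`, `type` (one of
#'   `integer`, `real`, `text`, `blob`, `timestamp`) and `nullable`
#' @param primary_key character vector of key column names
#' @param pk_autogenerated is the key assigned by the database on insert?
#' @return an object of class `table_descriptor`; audit columns
#'   (`creationdate`, `modificationdate`, detected by exact lowercase name
#'   match among timestamp-typed columns) are recorded in `audit_columns`
#' @export
table_descriptor <- function(table_name, columns, primary_key,
                             pk_autogenerated = FALSE) {
  stopifnot(
    is.data.frame(columns),
    all(c("name", "type", "nullable") %in% names(columns))
  )
  bad <- setdiff(columns$type, c("integer", "real", "text", "blob", "timestamp"))
  if (length(bad)) {
    pu_stop("unsupported_type", "unknown column type(s): ", paste(bad, collapse = ", "))
  }
  if (!all(primary_key %in% columns$name)) {
    pu_stop(
      "invalid_descriptor",
      "primary key column(s) absent from column list: ",
      paste(setdiff(primary_key, columns$name), collapse = ", ")
    )
  }
  named_audit <- intersect(audit_column_names, columns$name)
  audit <- named_audit[
    columns$type[match(named_audit, columns$name)] == "timestamp"
  ]
  if (length(setdiff(named_audit, audit))) {
    pu_warn(
      "audit_type",
      "column(s) ", paste(setdiff(named_audit, audit), collapse = ", "),
      " have audit names but are not timestamp-typed; not treated as audit columns"
    )
  }
  structure(
    list(
      table_name = table_name,
      columns = columns[, c("name", "type", "nullable")],
      primary_key = as.character(primary_key),
      pk_autogenerated = isTRUE(pk_autogenerated),
      audit_columns = audit
    ),
    class = "table_descriptor"
  )
}

#' @export
print.table_descriptor <- function(x, ...) {
  cat(sprintf(
    "<table_descriptor> %s: %d column(s), pk = {%s}%s%s\n",
    x$table_name, nrow(x$columns), paste(x$primary_key, collapse = ", "),
    if (x$pk_autogenerated) " (autogenerated)" else "",
    if (length(x$audit_columns)) {
      paste0(", audit = {", paste(x$audit_columns, collapse = ", "), "}")
    } else ""
  ))
  invisible(x)
}

#' Introspect a relational table
#'
#' Reads column names, mapped types, nullability, the primary key and
#' whether it is database-assigned, and detects the audit columns
#' `creationdate` / `modificationdate` by exact name match.
#'
#' @param con a DBI connection to the embedded database
#' @param table_name name of an existing table
#' @return a [table_descriptor()]
#' @export
introspect <- function(con, table_name) {
  if (!DBI::dbExistsTable(con, table_name)) {
    pu_stop("unknown_table", "table \"", table_name, "\" does not exist")
  }
  info <- DBI::dbGetQuery(
    con, sprintf("PRAGMA table_info(%s)", DBI::dbQuoteIdentifier(con, table_name))
  )
  types <- vapply(
    seq_len(nrow(info)),
    function(i) sql_type_map(info$type[i], info$name[i]),
    character(1L)
  )
  pk_cols <- info$name[info$pk > 0L][order(info$pk[info$pk > 0L])]
  # in SQLite a single INTEGER PRIMARY KEY aliases the rowid and is
  # assigned by the engine; that is the autogenerated-key case
  auto <- length(pk_cols) == 1L &&
    types[match(pk_cols, info$name)] == "integer"
  table_descriptor(
    table_name,
    data.frame(
      name = info$name, type = types, nullable = info$notnull == 0L,
      stringsAsFactors = FALSE
    ),
    primary_key = pk_cols,
    pk_autogenerated = auto
  )
}

# canonical text form of a descriptor, hashed into the provenance header
descriptor_fingerprint <- function(d) {
  canon <- paste(
    d$table_name,
    paste(d$columns$name, d$columns$type, d$columns$nullable,
          sep = ":", collapse = ";"),
    paste(d$primary_key, collapse = ","),
    d$pk_autogenerated,
    paste(d$audit_columns, collapse = ","),
    sep = "|"
  )
  f <- tempfile()
  on.exit(unlink(f))
  writeChar(canon, f, eos = NULL)
  unname(tools::md5sum(f))
}

quote_ident <- function(x) paste0("\"", gsub("\"", "\"\"", x), "\"")

#' Generate accessor source code for a table
#'
#' Emits R source defining a factory `<namespace>.<table>_accessor()`.
#' The produced accessor holds one attribute per column plus dirty and
#' persisted flags and implements four persistence operations:
#'
#' * `persist(con, clock)`: INSERT; reads back a database-assigned key;
#'   sets `creationdate` and `modificationdate` when present;
#' * `update(con, clock)`: UPDATE by primary key; refreshes
#'   `modificationdate` only; no-op (0 rows) when the instance is not
#'   dirty;
#' * `retrieve(con, key)`: SELECT by primary key, returns `TRUE` when the
#'   row was found and loaded, `FALSE` when absent;
#' * `delete(con)`: DELETE by primary key, returns the number of rows
#'   removed.
#'
#' Every value is bound as a statement parameter — no value is ever
#' interpolated into SQL text — so caller code contains no SQL at all.
#' Timestamps come from an injectable clock (UTC, microsecond precision)
#' for testable determinism. Generation is a pure function of the
#' descriptor: identical descriptors yield byte-identical source.
#'
#' @param descriptor a [table_descriptor()]
#' @param output_namespace prefix for the generated factory name
#' @return the generated source as a single string
#' @export
generate <- function(descriptor, output_namespace = "dao") {
  d <- descriptor
  if (length(d$primary_key) == 0L) {
    pu_stop(
      "cannot_generate",
      "table \"", d$table_name, "\" has no primary key; the retrieval ",
      "contract requires one"
    )
  }
  if (d$pk_autogenerated && length(d$primary_key) > 1L) {
    pu_stop(
      "cannot_generate",
      "multi-column autogenerated keys are not supported"
    )
  }
  cols <- d$columns$name
  types <- stats::setNames(d$columns$type, cols)
  pk <- d$primary_key
  auto_pk <- if (d$pk_autogenerated) pk else character()
  insert_cols <- setdiff(cols, auto_pk)
  update_cols <- setdiff(cols, c(pk, "creationdate"))
  has_cd <- "creationdate" %in% d$audit_columns
  has_md <- "modificationdate" %in% d$audit_columns

  bind_expr <- function(col) {
    if (types[[col]] == "blob") {
      sprintf(".bind_blob(\"%s\")", col)
    } else {
      sprintf(".bind(\"%s\")", col)
    }
  }
  insert_sql <- sprintf(
    "INSERT INTO %s (%s) VALUES (%s)",
    quote_ident(d$table_name),
    paste(quote_ident(insert_cols), collapse = ", "),
    paste(rep("?", length(insert_cols)), collapse = ", ")
  )
  where_sql <- paste(paste0(quote_ident(pk), " = ?"), collapse = " AND ")
  update_sql <- sprintf(
    "UPDATE %s SET %s WHERE %s",
    quote_ident(d$table_name),
    paste(paste0(quote_ident(update_cols), " = ?"), collapse = ", "),
    where_sql
  )
  select_sql <- sprintf(
    "SELECT %s FROM %s WHERE %s",
    paste(quote_ident(cols), collapse = ", "),
    quote_ident(d$table_name), where_sql
  )
  delete_sql <- sprintf(
    "DELETE FROM %s WHERE %s", quote_ident(d$table_name), where_sql
  )
  factory <- paste0(output_namespace, ".", d$table_name, "_accessor")

  src <- c(
    sprintf("# Accessor for table '%s'.", d$table_name),
    sprintf("# Generated by protutils dao_codegen %s", as.character(utils::packageVersion("protutils"))),
    sprintf("# descriptor: %s", descriptor_fingerprint(d)),
    "#",
    "# Implements the four persistence operations persist / update /",
    "# retrieve / delete. All values are bound as statement parameters;",
    "# caller code never contains SQL. The only engine-specific shim is",
    "# the last-inserted-key query used for database-assigned keys.",
    "",
    sprintf("%s <- function() {", factory),
    "  .self <- new.env(parent = emptyenv())",
    sprintf("  .self$.columns <- c(%s)", paste(sprintf("\"%s\"", cols), collapse = ", ")),
    "  .self$.fields <- stats::setNames(vector(\"list\", length(.self$.columns)), .self$.columns)",
    "  .self$.dirty <- FALSE",
    "  .self$.persisted <- FALSE",
    "  .self$.default_clock <- function() {",
    "    format(Sys.time(), tz = \"UTC\", format = \"%Y-%m-%d %H:%M:%OS6\")",
    "  }",
    "  .bind <- function(col) {",
    "    v <- .self$.fields[[col]]",
    "    if (is.null(v)) NA else v",
    "  }",
    "  .bind_blob <- function(col) {",
    "    v <- .self$.fields[[col]]",
    "    if (is.null(v)) list(NULL) else list(v)",
    "  }",
    "  .self$get <- function(col) .self$.fields[[col]]",
    "  .self$set <- function(col, value) {",
    "    if (!col %in% .self$.columns) stop(\"unknown column: \", col)",
    "    .self$.fields[[col]] <- value",
    "    .self$.dirty <- TRUE",
    "    invisible(.self)",
    "  }",
    "  .self$is_dirty <- function() .self$.dirty",
    "  .self$is_persisted <- function() .self$.persisted",
    "  .self$persist <- function(con, clock = .self$.default_clock) {",
    if (has_cd || has_md) "    now <- clock()",
    if (has_cd) "    .self$.fields[[\"creationdate\"]] <- now",
    if (has_md) "    .self$.fields[[\"modificationdate\"]] <- now",
    sprintf("    DBI::dbExecute(con, %s,", deparse(insert_sql)),
    sprintf("      params = list(%s))", paste(vapply(insert_cols, bind_expr, character(1L)), collapse = ", ")),
    if (length(auto_pk)) sprintf(
      "    .self$.fields[[\"%s\"]] <- DBI::dbGetQuery(con, \"SELECT last_insert_rowid() AS k\")$k[[1L]]",
      auto_pk
    ),
    "    .self$.persisted <- TRUE",
    "    .self$.dirty <- FALSE",
    "    invisible(.self)",
    "  }",
    "  .self$update <- function(con, clock = .self$.default_clock) {",
    "    if (!.self$.dirty) return(invisible(0L))",
    if (has_md) "    .self$.fields[[\"modificationdate\"]] <- clock()",
    sprintf("    n <- DBI::dbExecute(con, %s,", deparse(update_sql)),
    sprintf(
      "      params = list(%s))",
      paste(
        c(vapply(update_cols, bind_expr, character(1L)),
          vapply(pk, bind_expr, character(1L))),
        collapse = ", "
      )
    ),
    "    .self$.dirty <- FALSE",
    "    invisible(n)",
    "  }",
    "  .self$retrieve <- function(con, key = NULL) {",
    "    if (!is.null(key)) {",
    "      key <- as.list(key)",
    sprintf("      names(key) <- c(%s)", paste(sprintf("\"%s\"", pk), collapse = ", ")),
    "      for (k in names(key)) .self$.fields[[k]] <- key[[k]]",
    "    }",
    sprintf("    row <- DBI::dbGetQuery(con, %s,", deparse(select_sql)),
    sprintf("      params = list(%s))", paste(vapply(pk, bind_expr, character(1L)), collapse = ", ")),
    "    if (nrow(row) == 0L) return(FALSE)",
    "    for (col in .self$.columns) {",
    "      v <- row[[col]][[1L]]",
    "      .self$.fields[[col]] <- if (is.null(v) || (length(v) == 1L && !is.list(v) && is.na(v))) NULL else v",
    "    }",
    "    .self$.persisted <- TRUE",
    "    .self$.dirty <- FALSE",
    "    TRUE",
    "  }",
    "  .self$delete <- function(con) {",
    sprintf("    n <- DBI::dbExecute(con, %s,", deparse(delete_sql)),
    sprintf("      params = list(%s))", paste(vapply(pk, bind_expr, character(1L)), collapse = ", ")),
    "    .self$.persisted <- FALSE",
    "    invisible(n)",
    "  }",
    "  class(.self) <- \"dao_accessor\"",
    "  .self",
    "}"
  )
  paste0(paste(src, collapse = "\n"), "\n")
}

#' Load generated accessor source and return its factory
#'
#' Evaluates the source emitted by [generate()] in a private environment
#' and returns the factory function.
#'
#' @param source generated source text
#' @return a function creating accessor instances
#' @export
load_accessor <- function(source) {
  env <- new.env(parent = baseenv())
  eval(parse(text = source), envir = env)
  fns <- ls(env)
  get(fns[endsWith(fns, "_accessor")][1L], envir = env)
}

#' Verify the full CRUD cycle of a generated accessor
#'
#' Exercises persist, retrieve, update and delete of a generated accessor
#' against a live connection and reports every checked property:
#' persist then retrieve returns equal column values (blobs byte-equal);
#' a mutated instance updated and re-retrieved reflects the change with a
#' strictly later `modificationdate` and an unchanged `creationdate`; a
#' clean update is a no-op; delete removes the row, a second delete
#' removes nothing, and retrieval after delete reports absence.
#'
#' @param source generated accessor source from [generate()]
#' @param con DBI connection with the target table present
#' @param values named list of initial column values (keys included only
#'   when the key is not database-assigned)
#' @param mutate named list of changed values for the update step
#' @param clock optional deterministic clock function; defaults to a
#'   strictly increasing microsecond counter
#' @param transaction wrap the whole cycle in a transaction
#' @return a list with `pass` (logical) and `steps` (named logical vector)
#' @export
crud_roundtrip <- function(source, con, values, mutate, clock = NULL,
                           transaction = FALSE) {
  factory <- load_accessor(source)
  if (is.null(clock)) {
    tick <- 0L
    clock <- function() {
      tick <<- tick + 1L
      sprintf("2026-01-01 00:00:%09.6f", tick * 1e-3)
    }
  }
  if (transaction) {
    DBI::dbBegin(con)
    on.exit(DBI::dbCommit(con))
  }
  steps <- c()
  note <- function(name, ok) steps[[name]] <<- isTRUE(ok)

  same <- function(a, b) {
    if (is.null(a) || is.null(b)) {
      return(is.null(a) && is.null(b))
    }
    if (is.raw(a) || is.raw(b)) {
      return(identical(as.raw(a), as.raw(b)))
    }
    if (is.numeric(a) && is.numeric(b)) {
      return(isTRUE(all.equal(as.numeric(a), as.numeric(b))))
    }
    identical(as.character(a), as.character(b))
  }

  acc <- factory()
  for (nm in names(values)) acc$set(nm, values[[nm]])
  acc$persist(con, clock = clock)
  note("persisted_flag", acc$is_persisted() && !acc$is_dirty())

  # every column the SELECT's WHERE clause needs is already in .fields
  # after persist (including a database-assigned key), so a fresh accessor
  # seeded with those fields re-reads this row
  fresh <- factory()
  for (col in acc$.columns) fresh$.fields[[col]] <- acc$.fields[[col]]
  got <- fresh$retrieve(con)
  note("retrieve_after_persist", got)
  for (nm in names(values)) {
    note(paste0("roundtrip_", nm), same(fresh$get(nm), values[[nm]]))
  }
  has_cd <- "creationdate" %in% acc$.columns
  has_md <- "modificationdate" %in% acc$.columns
  if (has_cd) note("creationdate_set", !is.null(fresh$get("creationdate")))
  if (has_md) note("modificationdate_set", !is.null(fresh$get("modificationdate")))

  # clean update is a no-op
  n0 <- fresh$update(con, clock = clock)
  note("noop_update_zero_rows", identical(n0, 0L))
  md_before <- if (has_md) fresh$get("modificationdate")
  cd_before <- if (has_cd) fresh$get("creationdate")

  for (nm in names(mutate)) fresh$set(nm, mutate[[nm]])
  n1 <- fresh$update(con, clock = clock)
  note("update_one_row", identical(as.integer(n1), 1L))
  back <- factory()
  for (col in acc$.columns) back$.fields[[col]] <- fresh$.fields[[col]]
  note("retrieve_after_update", back$retrieve(con))
  for (nm in names(mutate)) {
    note(paste0("updated_", nm), same(back$get(nm), mutate[[nm]]))
  }
  if (has_md) {
    note("modificationdate_refreshed", back$get("modificationdate") > md_before)
  }
  if (has_cd) {
    note("creationdate_untouched", same(back$get("creationdate"), cd_before))
  }

  note("delete_one_row", identical(as.integer(back$delete(con)), 1L))
  gone <- factory()
  for (col in acc$.columns) gone$.fields[[col]] <- back$.fields[[col]]
  note("absent_after_delete", identical(gone$retrieve(con), FALSE))
  note("second_delete_zero_rows", identical(as.integer(back$delete(con)), 0L))

  list(pass = all(unlist(steps)), steps = unlist(steps))
}
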