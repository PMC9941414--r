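/* Minimal HDF5 I/O for raw camera stacks: one uint16 dataset "data" of
 * shape (n_frames, H, W) plus a string attribute carrying the serialized
 * acquisition metadata. Values cross the R boundary as a flat integer
 * vector already laid out in C (row-major) order; layout conversion is
 * done on the R side so the two storage backends share it. */

#include <hdf5.h>
#include <R.h>
#include <Rinternals.h>
#include <string.h>
#include <stdlib.h>

static void h5_stop(const char *msg, const char *path)
{
    error("HDF5 error: %s (%s)", msg, path ? path : "");
}

/* write attribute `name` = `value` (UTF-8 string, scalar) on object obj */
static void write_string_attr(hid_t obj, const char *name, const char *value)
{
    hid_t atype = H5Tcopy(H5T_C_S1);
    H5Tset_size(atype, strlen(value) + 1);
    H5Tset_cset(atype, H5T_CSET_UTF8);
    hid_t aspace = H5Screate(H5S_SCALAR);
    hid_t attr = H5Acreate2(obj, name, atype, aspace, H5P_DEFAULT, H5P_DEFAULT);
    if (attr < 0) { H5Sclose(aspace); H5Tclose(atype); h5_stop("attribute create failed", name); }
    H5Awrite(attr, atype, value);
    H5Aclose(attr);
    H5Sclose(aspace);
    H5Tclose(atype);
}

SEXP C_h5_write_stack(SEXP r_path, SEXP r_data, SEXP r_dims, SEXP r_attr_name,
                      SEXP r_attr_json)
{
    const char *path = CHAR(STRING_ELT(r_path, 0));
    const int *dims = INTEGER(r_dims);           /* n, H, W */
    hsize_t hdims[3] = { (hsize_t)dims[0], (hsize_t)dims[1], (hsize_t)dims[2] };
    R_xlen_t len = (R_xlen_t)dims[0] * dims[1] * dims[2];
    if (XLENGTH(r_data) != len)
        error("data length does not match dims");

    unsigned short *buf = (unsigned short *) R_alloc(len, sizeof(unsigned short));
    const int *src = INTEGER(r_data);
    for (R_xlen_t i = 0; i < len; i++) {
        int v = src[i];
        if (v < 0 || v > 65535) error("uint16 overflow at element %lld", (long long)i);
        buf[i] = (unsigned short) v;
    }

    hid_t file = H5Fcreate(path, H5F_ACC_TRUNC, H5P_DEFAULT, H5P_DEFAULT);
    if (file < 0) h5_stop("cannot create file", path);
    hid_t space = H5Screate_simple(3, hdims, NULL);
    hid_t dset = H5Dcreate2(file, "data", H5T_STD_U16LE, space,
                            H5P_DEFAULT, H5P_DEFAULT, H5P_DEFAULT);
    if (dset < 0) { H5Sclose(space); H5Fclose(file); h5_stop("cannot create dataset", path); }
    if (H5Dwrite(dset, H5T_NATIVE_USHORT, H5S_ALL, H5S_ALL, H5P_DEFAULT, buf) < 0) {
        H5Dclose(dset); H5Sclose(space); H5Fclose(file);
        h5_stop("dataset write failed", path);
    }
    write_string_attr(dset, CHAR(STRING_ELT(r_attr_name, 0)),
                      CHAR(STRING_ELT(r_attr_json, 0)));
    H5Dclose(dset);
    H5Sclose(space);
    H5Fclose(file);
    return r_path;
}

SEXP C_h5_read_stack(SEXP r_path, SEXP r_attr_name)
{
    const char *path = CHAR(STRING_ELT(r_path, 0));
    hid_t file = H5Fopen(path, H5F_ACC_RDONLY, H5P_DEFAULT);
    if (file < 0) h5_stop("cannot open file", path);
    hid_t dset = H5Dopen2(file, "data", H5P_DEFAULT);
    if (dset < 0) { H5Fclose(file); h5_stop("missing dataset 'data'", path); }
    hid_t space = H5Dget_space(dset);
    int rank = H5Sget_simple_extent_ndims(space);
    if (rank != 3) {
        H5Sclose(space); H5Dclose(dset); H5Fclose(file);
        h5_stop("dataset 'data' is not 3-dimensional", path);
    }
    hsize_t hdims[3];
    H5Sget_simple_extent_dims(space, hdims, NULL);
    R_xlen_t len = (R_xlen_t)hdims[0] * hdims[1] * hdims[2];

    unsigned short *buf = (unsigned short *) R_alloc(len, sizeof(unsigned short));
    if (H5Dread(dset, H5T_NATIVE_USHORT, H5S_ALL, H5S_ALL, H5P_DEFAULT, buf) < 0) {
        H5Sclose(space); H5Dclose(dset); H5Fclose(file);
        h5_stop("dataset read failed", path);
    }

    /* attribute: read as a string of whatever size it was stored with */
    const char *attr_name = CHAR(STRING_ELT(r_attr_name, 0));
    SEXP r_attr = R_NilValue;
    if (H5Aexists(dset, attr_name) > 0) {
        hid_t attr = H5Aopen(dset, attr_name, H5P_DEFAULT);
        hid_t atype = H5Aget_type(attr);
        size_t asize = H5Tget_size(atype);
        char *aval = (char *) R_alloc(asize + 1, 1);
        memset(aval, 0, asize + 1);
        H5Aread(attr, atype, aval);
        r_attr = mkString(aval);
        H5Tclose(atype);
        H5Aclose(attr);
    }

    SEXP r_data = PROTECT(allocVector(INTSXP, len));
    int *dst = INTEGER(r_data);
    for (R_xlen_t i = 0; i < len; i++) dst[i] = (int) buf[i];
    SEXP r_dims = PROTECT(allocVector(INTSXP, 3));
    INTEGER(r_dims)[0] = (int) hdims[0];
    INTEGER(r_dims)[1] = (int) hdims[1];
    INTEGER(r_dims)[2] = (int) hdims[2];

    SEXP out = PROTECT(allocVector(VECSXP, 3));
    SET_VECTOR_ELT(out, 0, r_data);
    SET_VECTOR_ELT(out, 1, r_dims);
    SET_VECTOR_ELT(out, 2, r_attr);
    SEXP nms = PROTECT(allocVector(STRSXP, 3));
    SET_STRING_ELT(nms, 0, mkChar("data"));
    SET_STRING_ELT(nms, 1, mkChar("dims"));
    SET_STRING_ELT(nms, 2, mkChar("attr"));
    setAttrib(out, R_NamesSymbol, nms);
    H5Sclose(space);
    H5Dclose(dset);
    H5Fclose(file);
    UNPROTECT(4);
    return out;
}

static const R_CallMethodDef call_entries[] = {
    {"C_h5_write_stack", (DL_FUNC) &C_h5_write_stack, 5},
    {"C_h5_read_stack",  (DL_FUNC) &C_h5_read_stack,  2},
    {NULL, NULL, 0}
};

void R_init_scopeflow(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
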