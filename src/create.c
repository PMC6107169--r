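/* Create an HDF5 file holding one chunked float64 dataset named "Data".
 *
 * rhdf5 handles all reads and writes, but its R API does not expose the
 * file-access alignment property (H5Pset_alignment), which is needed to
 * place every chunk on a stripe boundary. Creation therefore happens here:
 * the alignment property is set on the file-access list and chunk storage
 * is allocated early (at create time, under the aligned access list), so
 * later writes through any driver fill pre-placed, aligned chunks.
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include "hdf5.h"

#define MAX_RANK 32

SEXP C_h5_create_chunked(SEXP r_path, SEXP r_dims, SEXP r_chunk,
                         SEXP r_alignment)
{
    const char *path = CHAR(STRING_ELT(r_path, 0));
    int rank = LENGTH(r_dims);
    hsize_t dims[MAX_RANK], cdims[MAX_RANK];
    double *dd = REAL(r_dims), *cd = REAL(r_chunk);
    double align = REAL(r_alignment)[0];
    hid_t fapl, fid, sid, dcpl, did;
    int i;

    if (rank < 1 || rank > MAX_RANK || LENGTH(r_chunk) != rank)
        error("dims and chunk must have matching length in 1..%d", MAX_RANK);
    for (i = 0; i < rank; i++) {
        if (dd[i] < 1 || cd[i] < 1 || cd[i] > dd[i])
            error("chunk dims must satisfy 1 <= chunk <= dims");
        dims[i] = (hsize_t) dd[i];
        cdims[i] = (hsize_t) cd[i];
    }

    fapl = H5Pcreate(H5P_FILE_ACCESS);
    if (align > 0)
        H5Pset_alignment(fapl, 1, (hsize_t) align);
    fid = H5Fcreate(path, H5F_ACC_TRUNC, H5P_DEFAULT, fapl);
    H5Pclose(fapl);
    if (fid < 0)
        error("unable to create HDF5 file '%s'", path);

    sid = H5Screate_simple(rank, dims, NULL);
    dcpl = H5Pcreate(H5P_DATASET_CREATE);
    H5Pset_chunk(dcpl, rank, cdims);
    /* allocate (and fill) all chunks now, while the aligned fapl is live */
    H5Pset_alloc_time(dcpl, H5D_ALLOC_TIME_EARLY);
    H5Pset_fill_time(dcpl, H5D_FILL_TIME_ALLOC);
    did = H5Dcreate2(fid, "Data", H5T_IEEE_F64LE, sid, H5P_DEFAULT, dcpl,
                     H5P_DEFAULT);
    H5Pclose(dcpl);
    H5Sclose(sid);
    if (did < 0) {
        H5Fclose(fid);
        error("unable to create dataset in '%s'", path);
    }
    H5Dclose(did);
    H5Fclose(fid);
    return R_NilValue;
}

static const R_CallMethodDef call_entries[] = {
    {"C_h5_create_chunked", (DL_FUNC) &C_h5_create_chunked, 4},
    {NULL, NULL, 0}
};

void R_init_h5layout(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
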