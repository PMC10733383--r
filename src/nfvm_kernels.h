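#ifndef NFVM_KERNELS_H
#define NFVM_KERNELS_H

// raw energy/gradient kernels shared between the exported wrappers and the
// compiled L-BFGS minimizer

double energy2d_raw(const double* x, const double* y, const int* cptr,
                    const int* cv, int nc, const double* p0, double kp);
double grad2d_raw(const double* x, const double* y, const int* cptr,
                const int* cv, int nc, const double* p0, double kp,
                double* gx, double* gy);

double energy3d_raw(const double* px, const double* py, const double* pz,
                    const int* cptr, const int* av, const int* bv,
                    const double* xoff, int nc, const double* p0,
                    double alpha, double beta, double kp, double kV,
                    double* scratch5);
double grad3d_raw(const double* px, const double* py, const double* pz,
                const int* cptr, const int* av, const int* bv,
                const double* xoff, int nc, const double* p0, double alpha,
                double beta, double kp, double kV, double* scratch5,
                double* gx, double* gy, double* gz);

#endif
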