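observer,sigma_mx_ft,sigma_mx_st,sigma_mx_nt,sigma_my_ft,sigma_my_st,sigma_my_nt,sigma_v_50,sigma_v_300,sigma_v_1000,sigma_f,sigma_pi_x,sigma_pi_y,pi_x,pi_y,p_c
1,1.56,1.65,2.49,1.08,1.32,2.86,3.11,2.25,1.42,4.76,16.56,12.56,12.62,15.92,0.57
2,1.22,1.6,1.14,0.41,0.53,1.67,3.51,3.35,3.33,3.38,5.55,4.86,12.84,20.53,0.02
3,0.85,0.88,0.9,0.46,0.46,1.25,3.12,3.11,3.06,3.92,9.86,16.04,4.77,-0.53,0.78
4,0.9,1.05,1.24,0.88,0.69,1.45,1.39,1.17,0.07,4.29,19.36,11.12,9.22,0.5,0.09
5,1.3,1.04,1.16,0.78,0.81,1.78,1.53,1.35,0.14,3.66,17.82,11.28,1.11,12.23,0.21
6,0.87,0.98,1.16,0.49,0.38,1.27,3.39,3.23,3.1,4.57,3.61,20.3,7.65,2.43,0.62
7,1.68,0.83,1.02,0.62,0.48,2.27,0.9,0.47,0.26,6.65,23.93,14.29,6.1,-0.34,0.02
8,2.46,1.86,1.79,2.3,1.26,2.93,1.96,1.34,0.18,5.15,7.75,2.98,3.11,3.12,0.53
9,1.79,1.29,1.73,1.22,1.1,2.64,1.81,1.61,1.48,5.09,7.82,7.71,2.05,1.03,0.39
10,1.46,1.84,2.26,0.75,0.77,2.31,2.49,2.31,1.87,4.63,9.04,10.76,13.64,10.15,0.73
11,1.37,2.04,2.9,0.68,0.57,1.69,3.99,3.9,3.83,4.39,14.35,10.62,0.76,3.93,0.96
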