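compound,endpoint,dose,mean,dispersion,dispersion_type,n,direction
NIV,white blood cell count,0,9.1774,1.4328,SD,10,decrease
NIV,white blood cell count,300,10.2856,1.9348,SD,10,decrease
NIV,white blood cell count,900,9.286,1.0079,SD,10,decrease
NIV,white blood cell count,2700,7.9746,0.8103,SD,10,decrease
NIV,white blood cell count,8100,5.3144,1.1167,SD,10,decrease
T2,white blood cell count,0,10.3424,0.4068,SEM,10,decrease
T2,white blood cell count,2.142857142857143,10.2134,0.5805,SEM,10,decrease
T2,white blood cell count,6.428571428571429,8.7628,0.4692,SEM,10,decrease
T2,white blood cell count,19.285714285714285,8.0252,0.3634,SEM,10,decrease
T2,white blood cell count,57.857142857142854,5.2329,0.3846,SEM,10,decrease
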