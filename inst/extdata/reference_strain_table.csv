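point,load_50,load_150,load_250,load_350,load_450,load_550
1,3.08e-5,8.57e-5,1.14e-4,1.97e-4,2.62e-4,3.31e-4
2,6.94e-5,1.27e-4,1.89e-4,2.52e-4,3.26e-4,3.97e-4
3,1.76e-4,4.68e-4,7.70e-4,1.07e-3,1.41e-3,1.77e-3
4,6.07e-5,1.14e-4,1.76e-4,2.44e-4,3.21e-4,4.18e-4
5,3.83e-5,1.15e-4,1.88e-4,2.59e-4,3.34e-4,4.09e-4
6,3.51e-5,6.88e-5,1.23e-4,1.76e-4,2.32e-4,2.85e-4
7,9.54e-5,4.11e-4,7.21e-4,1.02e-3,1.32e-3,1.61e-3
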