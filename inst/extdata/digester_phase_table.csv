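digester,phase,parameter,value
D1,P1,propionate,826.60
D1,P1,acetate,105.99
D1,P1,butyrate,0.00
D1,P1,pH,6.82
D1,P1,N_NH3,483.80
D1,P1,COD,27595.16
D1,P1,BMP,0
D1,P2,propionate,739.78
D1,P2,acetate,1115.62
D1,P2,butyrate,33.57
D1,P2,pH,7.77
D1,P2,N_NH3,789.40
D1,P2,COD,12392.50
D1,P2,BMP,142.69
D1,P3,propionate,18.49
D1,P3,acetate,65.78
D1,P3,butyrate,0.00
D1,P3,pH,8.05
D1,P3,N_NH3,1107.25
D1,P3,COD,3959.78
D1,P3,BMP,216.63
D2,P1,propionate,922.86
D2,P1,acetate,233.48
D2,P1,butyrate,84.35
D2,P1,pH,6.86
D2,P1,N_NH3,479.75
D2,P1,COD,25457.29
D2,P1,BMP,0
D2,P2,propionate,494.45
D2,P2,acetate,685.91
D2,P2,butyrate,31.25
D2,P2,pH,7.79
D2,P2,N_NH3,844.90
D2,P2,COD,11204.79
D2,P2,BMP,139.95
D2,P3,propionate,16.00
D2,P3,acetate,312.87
D2,P3,butyrate,0.00
D2,P3,pH,8.01
D2,P3,N_NH3,1302.35
D2,P3,COD,4316.09
D2,P3,BMP,191.52
D3,P1,propionate,860.45
D3,P1,acetate,349.16
D3,P1,butyrate,93.02
D3,P1,pH,6.84
D3,P1,N_NH3,501.20
D3,P1,COD,26526.22
D3,P1,BMP,0
D3,P2,propionate,32.44
D3,P2,acetate,185.83
D3,P2,butyrate,0.00
D3,P2,pH,7.74
D3,P2,N_NH3,1217.00
D3,P2,COD,3484.69
D3,P2,BMP,135.74
D3,P3,propionate,17.33
D3,P3,acetate,311.68
D3,P3,butyrate,12.84
D3,P3,pH,7.94
D3,P3,N_NH3,1146.05
D3,P3,COD,5503.80
D3,P3,BMP,155.49
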