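id,age,sex,bmi,Ala_T1,Ala_T2,Ala_T3,Ala_T4,Gly_T1,Gly_T2,Gly_T3,Gly_T4
P01,47.4,0,25.1,457.68,436.36,433.72,463.09,259.42,227.46,259.51,218.35
P02,40.9,0,22.6,454.29,386.85,422.09,411.81,193.53,234.18,211.84,179.07
P03,33.6,0,22.3,406,,462.2,390.1,208.37,260.85,233.97,203.78
P04,32.3,1,25.4,393.84,435.24,376.21,410.27,190.18,203.47,147.22,183.6
P05,49.6,0,21.4,436.75,423.24,568.25,496.44,230.15,202.64,211.83,224.76
P06,51.3,0,24.1,403.97,378.6,395.31,379.39,252.95,232.84,238.14,248.16
P07,41.7,1,25.6,273.02,291.09,319.63,309.71,235.85,252.33,266.94,
P08,33.4,1,30.2,419.53,380.26,426.17,482.03,199.73,187.93,156.98,191.34
P09,19.6,0,20.4,391.41,469.7,429.11,401.14,157.83,170.34,165.96,187.18
P10,20.9,0,24.5,338.88,334.16,280.86,299.27,134.1,189.77,194.07,192.86
P11,13.9,0,25.1,470.27,445.9,429.95,457.96,33.16,159.04,170.33,137.62
P12,40.9,0,26.2,285.81,375,400.09,296.03,173.87,140.97,144.98,165.49
P13,45.5,0,26.1,370.09,397.11,430.99,441.75,242.01,229.98,161.02,251.97
P14,38.7,0,30.1,375.34,400.86,432.65,476.6,238.56,252.79,240.71,288.83
P15,-6.3,0,22.4,419.9,381.69,472.85,409.74,195.71,244.74,199.25,193.37
P16,33.1,0,21.7,410.67,370.21,380.28,403.9,252.22,253.58,243.45,245.32
P17,23.3,0,22.1,518.4,430.79,478.3,437.45,222.4,215.94,252.2,280.14
P18,40.7,1,20.9,418.32,405.98,436.62,411.34,284.05,293.95,269.79,236.23
P19,14.8,1,22,385.19,321.69,319.78,365.84,285.83,268.35,304.84,290.92
P20,9.7,1,19.7,396.66,360.14,391.58,427.57,137.95,146.23,135.3,157.42
P21,49.4,0,26.8,305.18,326.06,414.94,380.4,207.72,179.01,173.51,239.87
P22,39,0,23.4,440.69,445.04,466.79,434.43,228.6,226.44,202.24,191.89
P23,48.1,0,27.2,423.23,400.12,406.21,450.68,175.37,220.71,191.77,145.63
P24,32.3,0,24,359.63,328.99,236.44,313.64,216.71,209.54,205.99,208.65
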